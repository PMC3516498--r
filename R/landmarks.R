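#' Named anatomical landmarks
#'
#' A set of named 3-D world points (mm). The canonical reorientation needs
#' `right_entry_dorsal` and `left_entry_dorsal` — the most dorsal points of
#' the right and left orbital entries, whose connecting line defines the
#' measurement frame. Optional rim landmarks (`right_rim_superior`,
#' `right_rim_inferior`, `left_rim_superior`, `left_rim_inferior`)
#' determine the roll about the inter-orbital axis; without them roll is
#' fixed at zero.
#'
#' @param points Named list of numeric 3-vectors (world mm).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points) {
  required <- c("right_entry_dorsal", "left_entry_dorsal")
  optional <- c("right_rim_superior", "right_rim_inferior",
                "left_rim_superior", "left_rim_inferior")
  if (!is.list(points) || is.null(names(points)))
    stop("landmark_set: 'points' must be a named list", call. = FALSE)
  missing_req <- setdiff(required, names(points))
  if (length(missing_req))
    stop("landmark_set: missing required landmark(s) ",
         paste(missing_req, collapse = ", "),
         "; required names are: ", paste(required, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(names(points), c(required, optional))
  if (length(unknown))
    stop("landmark_set: unknown landmark name(s) ",
         paste(unknown, collapse = ", "), "; allowed names are: ",
         paste(c(required, optional), collapse = ", "), call. = FALSE)
  points <- lapply(points, as.numeric)
  bad <- names(points)[vapply(points, function(p)
    length(p) != 3L || anyNA(p), logical(1))]
  if (length(bad))
    stop("landmark_set: landmark(s) ", paste(bad, collapse = ", "),
         " are not finite 3-vectors", call. = FALSE)
  r <- points$right_entry_dorsal; l <- points$left_entry_dorsal
  if (sqrt(sum((r - l)^2)) < 1e-9)
    stop("landmark_set: right_entry_dorsal and left_entry_dorsal coincide",
         call. = FALSE)
  if (abs(r[1] - l[1]) < 1e-9)
    stop("landmark_set: entry-dorsal landmarks must differ in the ",
         "left-right coordinate", call. = FALSE)
  structure(points, class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set with", length(x), "points:\n")
  for (nm in names(x))
    cat("  ", nm, ": (", paste(format(x[[nm]], digits = 5), collapse = ", "),
        ") mm\n", sep = "")
  invisible(x)
}

#' Write or read landmarks as JSON
#'
#' JSON layout: `{"name": [x_mm, y_mm, z_mm], ...}`.
#'
#' @param lm A [landmark_set()].
#' @param path File path.
#' @return `read_landmarks` returns a [landmark_set()].
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  jsonlite::write_json(unclass(lm), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    stop("read_landmarks: file not found: ", path, call. = FALSE)
  landmark_set(jsonlite::read_json(path, simplifyVector = TRUE))
}
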