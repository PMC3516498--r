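#' Rigid transform in world coordinates
#'
#' A rigid (proper) transform `x' = R x + t` acting on world coordinates in
#' millimetres. The rotation must be orthonormal with determinant +1.
#'
#' @param rotation 3x3 orthonormal rotation matrix.
#' @param translation numeric length-3 translation in mm.
#' @return An object of class `rigid_transform`.
#' @export
#' @examples
#' t <- rigid_transform(diag(3), c(1, 0, 0))
#' apply_transform(t, c(0, 0, 0))
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || anyNA(rotation))
    stop("rigid_transform: 'rotation' must be a numeric 3x3 matrix", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rigid_transform: 'rotation' is not orthonormal", call. = FALSE)
  if (det(rotation) < 0)
    stop("rigid_transform: 'rotation' has determinant -1 (reflection)", call. = FALSE)
  if (length(translation) != 3L || anyNA(translation))
    stop("rigid_transform: 'translation' must be a numeric 3-vector", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  rotation angle:",
      format(rotation_angle(x), digits = 6), "deg\n  translation:",
      paste(format(x$translation, digits = 6), collapse = ", "), "mm\n")
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param t A [rigid_transform()].
#' @param pts Numeric 3-vector or n-by-3 matrix of world points (mm).
#' @return Transformed points with the same shape as `pts`.
#' @export
apply_transform <- function(t, pts) {
  stopifnot(inherits(t, "rigid_transform"))
  if (is.null(dim(pts))) {
    as.numeric(t$rotation %*% pts + t$translation)
  } else {
    sweep(pts %*% t(t$rotation), 2, t$translation, "+")
  }
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `t1` first, then `t2`.
#'
#' @param t2,t1 [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(t2, t1) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t2$rotation %*% t1$translation) + t2$translation)
}

#' Invert a rigid transform
#'
#' @param t A [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(t) {
  rt <- t(t$rotation)
  rigid_transform(rt, -as.numeric(rt %*% t$translation))
}

#' Rotation angle of a rigid transform
#'
#' @param t A [rigid_transform()].
#' @return Rotation angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(t) {
  ctheta <- (sum(diag(t$rotation)) - 1) / 2
  acos(min(1, max(-1, ctheta))) * 180 / pi
}

#' Rotation about a coordinate axis
#'
#' @param axis One of `"x"` (left-right), `"y"` (posterior-anterior),
#'   `"z"` (inferior-superior).
#' @param angle_deg Rotation angle in degrees (right-handed).
#' @return A [rigid_transform()] with zero translation.
#' @export
rotation_about_axis <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  r <- switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
  rigid_transform(r, c(0, 0, 0))
}

# Minimal rotation mapping unit(u) onto unit(v) (Rodrigues), used to bring
# the inter-orbital landmark line onto the left-right axis.
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  k <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(k^2)); c_ <- sum(u * v)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 deg about any axis orthogonal to u
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    k <- c(u[2] * p[3] - u[3] * p[2],
           u[3] * p[1] - u[1] * p[3],
           u[1] * p[2] - u[2] * p[1])
    k <- k / sqrt(sum(k^2))
    return(2 * outer(k, k) - diag(3))
  }
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + kx + kx %*% kx * ((1 - c_) / s^2)
}

#' Write or read a rigid transform as JSON
#'
#' The JSON layout is `{"rotation": [9 numbers, row-major],
#' "translation": [3 numbers]}`.
#'
#' @param t A [rigid_transform()].
#' @param path Destination / source file path.
#' @return `read_transform` returns a [rigid_transform()];
#'   `write_transform` returns `path` invisibly.
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  jsonlite::write_json(
    list(rotation = as.numeric(t(t$rotation)), translation = t$translation),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path))
    stop("read_transform: file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$rotation) || length(x$rotation) != 9L)
    stop("read_transform: 'rotation' must hold 9 numbers (row-major)", call. = FALSE)
  rigid_transform(matrix(as.numeric(x$rotation), 3, 3, byrow = TRUE),
                  as.numeric(x$translation))
}
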