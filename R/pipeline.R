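#' Run the full single-case measurement pipeline
#'
#' Orchestrates align -> measure (both sides) -> compare -> classify for
#' one head volume: reorients the volume into the canonical frame from the
#' entry-dorsal landmarks, measures both orbits by serial coronal slices,
#' emulates the repeated-measures design by adding seeded rater noise to
#' the measured areas (see [simulate_repeated_measures()]), runs the
#' per-slice paired comparison and classifies the case.
#'
#' @param volume A [volume_image()] or path to a NIfTI file.
#' @param landmarks A [landmark_set()] or path to a landmark JSON file.
#' @param seed_left,seed_right World points (mm) inside the left/right
#'   cavities at the frame plane, in canonical-frame coordinates. Default:
#'   the aligned entry-dorsal landmarks.
#' @param operated Side carrying the implant (compared as "smaller?").
#' @param cfg A [protocol_config()].
#' @param noise_sd,rater_sd Rater noise model passed to
#'   [simulate_repeated_measures()].
#' @param rng_seed Integer seed for the rater-noise simulation.
#' @param case_id Identifier recorded in the report.
#' @return An object of class `case_report`: list with `case_id`,
#'   `areas` (per side/slice data frame), `volumes_mm3`, `p_values`,
#'   `flags`, `category`, `n_significant`, `atypical`, `transform`,
#'   `config`.
#' @export
run_pipeline <- function(volume, landmarks, seed_left = NULL,
                         seed_right = NULL, operated = c("left", "right"),
                         cfg = protocol_config(), noise_sd = 0.02,
                         rater_sd = 0, rng_seed = 1L, case_id = "case1") {
  operated <- match.arg(operated)
  if (is.character(volume)) volume <- read_volume(volume)
  if (is.character(landmarks)) landmarks <- read_landmarks(landmarks)
  stopifnot(inherits(volume, "volume_image"),
            inherits(landmarks, "landmark_set"))

  al <- align_volume(volume, landmarks)
  if (is.null(seed_left))
    seed_left <- apply_transform(al$transform, landmarks$left_entry_dorsal)
  if (is.null(seed_right))
    seed_right <- apply_transform(al$transform, landmarks$right_entry_dorsal)

  m_left <- measure_orbit(al$volume, "left", seed_left, cfg)
  m_right <- measure_orbit(al$volume, "right", seed_right, cfg)
  areas <- rbind(measurement_table(m_left), measurement_table(m_right))

  a_op <- areas$area_mm2[areas$side == operated]
  a_he <- areas$area_mm2[areas$side != operated]
  set.seed(rng_seed)
  rm <- simulate_repeated_measures(a_op, a_he, operated = operated,
                                   n_raters = cfg$n_raters,
                                   n_repeats = cfg$n_repeats,
                                   noise_sd = noise_sd, rater_sd = rater_sd,
                                   case_id = case_id)
  pat <- slice_significance(rm, cfg, operated = operated)
  cls <- classify_case(pat)

  structure(list(
    case_id = case_id,
    operated = operated,
    areas = areas,
    volumes_mm3 = c(left = m_left$volume_mm3, right = m_right$volume_mm3),
    p_values = pat$p_values,
    flags = pat$flags,
    category = cls$category,
    n_significant = cls$n_significant,
    atypical = cls$atypical,
    transform = al$transform,
    config = unclass(cfg),
    schema_version = "1"),
    class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat("case_report ", x$case_id, ": category ", x$category,
      " (", x$n_significant, " significant slice(s))\n", sep = "")
  print(x$areas, row.names = FALSE)
  cat("volumes (mm^3): left ", format(x$volumes_mm3[["left"]], digits = 7),
      ", right ", format(x$volumes_mm3[["right"]], digits = 7), "\n", sep = "")
  invisible(x)
}

#' Serialize a case report
#'
#' Deterministic serialization of a [run_pipeline()] report. JSON carries
#' the full report (schema version 1) and round-trips through
#' [read_report()]. CSV holds the per-slice area table (columns `side`,
#' `slice_index`, `plane_position_mm`, `area_mm2`, `n_bridged_gaps`).
#' HTML is a minimal static page with the same tables.
#'
#' @param report A `case_report`.
#' @param path Destination file.
#' @param format `"json"`, `"csv"` or `"html"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path, format = c("json", "csv", "html")) {
  stopifnot(inherits(report, "case_report"))
  format <- match.arg(format)
  if (format == "json") {
    x <- unclass(report)
    x$volumes_mm3 <- as.list(report$volumes_mm3)
    x$transform <- list(rotation = as.numeric(t(report$transform$rotation)),
                        translation = report$transform$translation)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  } else if (format == "csv") {
    write.csv(report$areas, path, row.names = FALSE)
  } else {
    tb <- report$areas
    rows <- apply(tb, 1, function(r)
      paste0("<tr><td>", paste(trimws(r), collapse = "</td><td>"), "</td></tr>"))
    html <- c("<html><head><title>Orbital measurement report</title></head><body>",
              paste0("<h1>Case ", report$case_id, "</h1>"),
              paste0("<p>Category ", report$category, " (",
                     report$n_significant, " significant slices)</p>"),
              "<table border='1'>",
              paste0("<tr><th>", paste(names(tb), collapse = "</th><th>"),
                     "</th></tr>"),
              rows,
              "</table>",
              paste0("<p>Volume left: ", report$volumes_mm3[["left"]],
                     " mm<sup>3</sup>, right: ", report$volumes_mm3[["right"]],
                     " mm<sup>3</sup></p>"),
              "</body></html>")
    writeLines(html, path)
  }
  invisible(path)
}

#' Reload a JSON case report
#'
#' @param path Path written by [render_report()] with `format = "json"`.
#' @return A `case_report`.
#' @export
read_report <- function(path) {
  if (!file.exists(path))
    stop("read_report: file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$transform <- rigid_transform(
    matrix(as.numeric(x$transform$rotation), 3, 3, byrow = TRUE),
    as.numeric(x$transform$translation))
  x$areas <- as.data.frame(x$areas)
  x$volumes_mm3 <- unlist(x$volumes_mm3)
  structure(x, class = "case_report")
}
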