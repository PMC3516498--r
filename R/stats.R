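#' Repeated-measures area table
#'
#' The unit fed to the per-slice paired comparison: one area per
#' (side, slice, rater, repeat) cell. Stored as a data frame with columns
#' `case_id`, `side` (`"left"`/`"right"`), `slice_index`, `rater`,
#' `replicate`, `area_mm2`.
#'
#' @param df Data frame with the columns above (a column named `repeat`
#'   is accepted and renamed to `replicate`).
#' @return A validated data frame of class `repeated_measures`.
#' @export
repeated_measures <- function(df) {
  df <- as.data.frame(df)
  nm <- names(df)
  nm[nm %in% c("repeat", "repeat.")] <- "replicate"
  names(df) <- nm
  need <- c("case_id", "side", "slice_index", "rater", "replicate", "area_mm2")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("repeated_measures: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!all(df$side %in% c("left", "right")))
    stop("repeated_measures: 'side' must be \"left\" or \"right\"", call. = FALSE)
  if (any(df$area_mm2 < 0))
    stop("repeated_measures: areas must be >= 0", call. = FALSE)
  # both sides present for every populated (slice, rater, replicate) cell
  key <- interaction(df$case_id, df$slice_index, df$rater, df$replicate,
                     drop = TRUE)
  sides_per_cell <- tapply(df$side, key, function(s) length(unique(s)))
  if (any(sides_per_cell != 2L))
    stop("repeated_measures: every (case, slice, rater, repeat) cell must ",
         "be measured on both sides", call. = FALSE)
  structure(df[need], class = c("repeated_measures", "data.frame"))
}

#' Read repeated measures from CSV
#'
#' Expects columns `case_id, side, slice_index, rater, repeat, area_mm2`.
#'
#' @param path CSV file path.
#' @return A [repeated_measures()] data frame.
#' @export
read_repeated_measures <- function(path) {
  if (!file.exists(path))
    stop("read_repeated_measures: file not found: ", path, call. = FALSE)
  repeated_measures(read.csv(path, check.names = FALSE))
}

#' Paired t-test on two sets of areas
#'
#' Classical paired t-test on the differences `a - b`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom and a
#' two-sided p-value. Zero variance of the differences is degenerate (the
#' t statistic is undefined or infinite) and raises an error; the all-zero
#' case can instead return the `t = 0, p = 1` convention when
#' `zero_diff = "zero"`.
#'
#' @param a,b Numeric vectors of equal length `n >= 2`.
#' @param zero_diff `"error"` (default) or `"zero"`: behaviour when every
#'   difference is exactly zero.
#' @return List with `statistic`, `df`, `p_value`, `mean_diff`.
#' @export
paired_t <- function(a, b, zero_diff = c("error", "zero")) {
  zero_diff <- match.arg(zero_diff)
  if (length(a) != length(b))
    stop("paired_t: 'a' and 'b' must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2L) stop("paired_t: need at least 2 pairs", call. = FALSE)
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0)) {
      if (zero_diff == "zero")
        return(list(statistic = 0, df = n - 1L, p_value = 1, mean_diff = 0))
      stop("paired_t: degenerate variance (all differences are zero)",
           call. = FALSE)
    }
    stop("paired_t: degenerate variance (constant non-zero differences, ",
         "|t| infinite)", call. = FALSE)
  }
  tt <- t.test(a, b, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Per-slice significance pattern of one case
#'
#' For each slice, pairs the `n_raters x n_repeats` area measurements of
#' the operated orbit with the corresponding (same rater, same repeat)
#' measurements of the healthy orbit and applies the paired t-test. A
#' slice is flagged iff its two-sided p-value is below `alpha` *and* the
#' operated mean area is below the healthy mean (the comparison looks for
#' a significantly smaller operated orbit). No multiple-testing correction
#' is applied across slices.
#'
#' @param rm A [repeated_measures()] data frame for one case.
#' @param cfg A [protocol_config()] (supplies `alpha` and `n_slices`).
#' @param operated Which side carries the implant (`"left"` or `"right"`).
#' @return An object of class `slice_pattern`: list with `case_id`,
#'   `flags` (logical, one per slice), `p_values`, `mean_operated`,
#'   `mean_healthy`, `operated`.
#' @export
slice_significance <- function(rm, cfg = protocol_config(),
                               operated = c("left", "right")) {
  stopifnot(inherits(rm, "repeated_measures"))
  operated <- match.arg(operated)
  healthy <- setdiff(c("left", "right"), operated)
  case_id <- unique(rm$case_id)
  if (length(case_id) != 1L)
    stop("slice_significance: 'rm' must contain exactly one case", call. = FALSE)
  slices <- sort(unique(rm$slice_index))
  if (length(slices) != cfg$n_slices)
    stop("slice_significance: expected ", cfg$n_slices, " slices, found ",
         length(slices), call. = FALSE)
  p <- mo <- mh <- numeric(length(slices))
  flags <- logical(length(slices))
  for (i in seq_along(slices)) {
    sl <- rm[rm$slice_index == slices[i], ]
    op <- sl[sl$side == operated, ]
    he <- sl[sl$side == healthy, ]
    key <- function(d) paste(d$rater, d$replicate)
    he <- he[match(key(op), key(he)), ]
    if (anyNA(he$area_mm2) || nrow(op) != nrow(he))
      stop("slice_significance: incomplete pairing at slice ", slices[i],
           call. = FALSE)
    tt <- paired_t(op$area_mm2, he$area_mm2)
    p[i] <- tt$p_value
    mo[i] <- mean(op$area_mm2); mh[i] <- mean(he$area_mm2)
    flags[i] <- p[i] < cfg$alpha && mo[i] < mh[i]
  }
  structure(list(case_id = case_id, flags = flags, p_values = p,
                 mean_operated = mo, mean_healthy = mh, operated = operated),
            class = "slice_pattern")
}

#' Construct a slice pattern from known flags
#'
#' Builds a `slice_pattern` directly from per-slice significance flags
#' (e.g. parsed from a published table); p-values are unknown (`NA`).
#'
#' @param case_id Case identifier.
#' @param flags Logical vector, one flag per slice (`TRUE` = operated
#'   orbit significantly smaller).
#' @return A `slice_pattern`.
#' @export
slice_pattern <- function(case_id, flags) {
  flags <- as.logical(flags)
  if (!length(flags) || anyNA(flags))
    stop("slice_pattern: 'flags' must be logical without NAs", call. = FALSE)
  structure(list(case_id = case_id, flags = flags,
                 p_values = rep(NA_real_, length(flags)),
                 mean_operated = rep(NA_real_, length(flags)),
                 mean_healthy = rep(NA_real_, length(flags)),
                 operated = NA_character_),
            class = "slice_pattern")
}

#' Classify a case by its significance pattern
#'
#' Category A: the first four (or all five) slices are significantly
#' smaller on the operated side — flags 1-4 all `TRUE`, flag 5 free.
#' Category C: no slice significant. Category B: everything else (one to
#' three significant slices in the typical case). Patterns with four or
#' more significant slices that still miss one of the first four are
#' category B but tagged `atypical`, since the A/B/C taxonomy does not
#' anticipate them.
#'
#' @param p A `slice_pattern`.
#' @return An object of class `case_category`: list with `category`
#'   (`"A"`, `"B"` or `"C"`), `n_significant`, `atypical`, `case_id`.
#' @export
classify_case <- function(p) {
  stopifnot(inherits(p, "slice_pattern"))
  f <- p$flags
  n_sig <- sum(f)
  category <- if (length(f) >= 4L && all(f[1:4])) "A"
              else if (n_sig == 0L) "C"
              else "B"
  structure(list(case_id = p$case_id, category = category,
                 n_significant = n_sig,
                 atypical = category == "B" && n_sig >= 4L),
            class = "case_category")
}

#' Tally case categories over a cohort
#'
#' @param patterns List of `slice_pattern` objects.
#' @return List with `count_A`, `count_B`, `count_C`, `n_cases`, and
#'   `per_slice_significant` (number of cases significant at each slice).
#' @export
summarize_cohort <- function(patterns) {
  if (!length(patterns))
    stop("summarize_cohort: empty cohort", call. = FALSE)
  stopifnot(all(vapply(patterns, inherits, logical(1), "slice_pattern")))
  cats <- vapply(patterns, function(p) classify_case(p)$category, character(1))
  flags <- do.call(rbind, lapply(patterns, `[[`, "flags"))
  list(count_A = sum(cats == "A"), count_B = sum(cats == "B"),
       count_C = sum(cats == "C"), n_cases = length(patterns),
       per_slice_significant = colSums(flags))
}

#' Rater reproducibility of repeated measurements
#'
#' Per (side, slice): the intra-rater coefficient of variation is the mean
#' over raters of sd/mean across that rater's repeats; the inter-rater CV
#' is sd/mean of the rater means.
#'
#' @param rm A [repeated_measures()] data frame (>= 2 raters, >= 2
#'   repeats).
#' @return Data frame with columns `side`, `slice_index`, `intra_rater_cv`,
#'   `inter_rater_cv`.
#' @export
rater_reproducibility <- function(rm) {
  stopifnot(inherits(rm, "repeated_measures"))
  if (length(unique(rm$rater)) < 2L || length(unique(rm$replicate)) < 2L)
    stop("rater_reproducibility: need >= 2 raters and >= 2 repeats",
         call. = FALSE)
  out <- expand.grid(side = sort(unique(rm$side)),
                     slice_index = sort(unique(rm$slice_index)),
                     stringsAsFactors = FALSE)
  out$intra_rater_cv <- out$inter_rater_cv <- NA_real_
  for (r in seq_len(nrow(out))) {
    cell <- rm[rm$side == out$side[r] & rm$slice_index == out$slice_index[r], ]
    if (any(tapply(cell$area_mm2, cell$rater, mean) == 0) ||
        mean(cell$area_mm2) == 0)
      stop("rater_reproducibility: zero mean area", call. = FALSE)
    per_rater <- tapply(cell$area_mm2, cell$rater, function(x) sd(x) / mean(x))
    rater_means <- tapply(cell$area_mm2, cell$rater, mean)
    out$intra_rater_cv[r] <- mean(per_rater)
    out$inter_rater_cv[r] <- sd(rater_means) / mean(rater_means)
  }
  out
}

#' Simulate repeated rater measurements of known slice areas
#'
#' Emulates the repeated-measures design (`n_raters` observers, each
#' measuring each slice `n_repeats` times on each side): each recorded
#' area is the true area plus a per-(rater, side) bias drawn with standard
#' deviation `rater_sd` plus independent per-measurement noise with
#' standard deviation `noise_sd`. Noise scales are given as fractions of
#' the true area, matching how tracing error grows with contour size.
#' Negative draws are truncated at zero.
#'
#' @param areas_operated,areas_healthy True per-slice areas (mm^2), equal
#'   length.
#' @param operated Which side is operated; the healthy areas are assigned
#'   to the other side.
#' @param n_raters,n_repeats Design size.
#' @param noise_sd Per-measurement noise, as a fraction of the true area
#'   (default 0.02).
#' @param rater_sd Per-(rater, side) systematic bias, as a fraction of the
#'   true area (default 0: raters unbiased).
#' @param case_id Case identifier for the output.
#' @return A [repeated_measures()] data frame.
#' @export
simulate_repeated_measures <- function(areas_operated, areas_healthy,
                                       operated = "left", n_raters = 3L,
                                       n_repeats = 3L, noise_sd = 0.02,
                                       rater_sd = 0, case_id = "case1") {
  stopifnot(length(areas_operated) == length(areas_healthy))
  healthy <- setdiff(c("left", "right"), operated)
  n_slices <- length(areas_operated)
  rows <- expand.grid(replicate = seq_len(n_repeats), rater = seq_len(n_raters),
                      slice_index = seq_len(n_slices),
                      side = c(operated, healthy), stringsAsFactors = FALSE)
  true_area <- ifelse(rows$side == operated,
                      areas_operated[rows$slice_index],
                      areas_healthy[rows$slice_index])
  bias_key <- paste(rows$side, rows$rater)
  biases <- rnorm(length(unique(bias_key)), 0, rater_sd)
  names(biases) <- unique(bias_key)
  area <- true_area * (1 + biases[bias_key] + rnorm(nrow(rows), 0, noise_sd))
  rows$area_mm2 <- pmax(as.numeric(area), 0)
  rows$case_id <- case_id
  repeated_measures(rows)
}

#' Read per-slice significance flags from CSV
#'
#' Parses a table of per-case slice flags (columns `case`,
#' `slice1` ... `sliceK`, values `yes`/`no`) into a list of
#' [slice_pattern()] objects, e.g. the bundled 20-case implant cohort:
#' `read_slice_flags(system.file("extdata", "implant_cohort_slice_flags.csv",
#' package = "orbitovol"))`.
#'
#' @param path CSV file path.
#' @return List of `slice_pattern` objects.
#' @export
read_slice_flags <- function(path) {
  if (!file.exists(path))
    stop("read_slice_flags: file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  slice_cols <- grep("^slice", names(df), value = TRUE)
  if (!"case" %in% names(df) || !length(slice_cols))
    stop("read_slice_flags: expected columns 'case' and 'slice1..K'",
         call. = FALSE)
  slice_cols <- slice_cols[order(as.integer(sub("^slice", "", slice_cols)))]
  lapply(seq_len(nrow(df)), function(i) {
    v <- tolower(unlist(df[i, slice_cols]))
    if (!all(v %in% c("yes", "no")))
      stop("read_slice_flags: flags must be yes/no", call. = FALSE)
    slice_pattern(df$case[i], v == "yes")
  })
}
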