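#' Measurement protocol configuration
#'
#' Parameters of the serial coronal slice protocol: five slices at 4.8 mm
#' ventrodorsal intervals from the orbital frame toward the apex, areas
#' compared at alpha = 0.05 over 3 raters x 3 repeats.
#'
#' @param n_slices Number of coronal slices (>= 1).
#' @param interval_mm Ventrodorsal slice spacing in mm (> 0).
#' @param alpha Significance level for per-slice paired tests.
#' @param bone_threshold Intensity threshold for bone, or `"auto"` for a
#'   two-class histogram split (see [bone_mask()]).
#' @param max_gap_mm Largest bony interruption (mm) that may be bridged
#'   with a straight chord; 10 mm covers the orbital fissures at adult
#'   scales.
#' @param n_raters,n_repeats Repeated-measures design for the statistical
#'   comparison.
#' @param frame_offset_mm Position of slice 1 relative to the orbital
#'   frame plane (y = 0 after alignment); 0 places slice 1 on the frame.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(n_slices = 5L, interval_mm = 4.8, alpha = 0.05,
                            bone_threshold = "auto", max_gap_mm = 10,
                            n_raters = 3L, n_repeats = 3L,
                            frame_offset_mm = 0) {
  if (n_slices < 1L) stop("protocol_config: 'n_slices' must be >= 1", call. = FALSE)
  if (interval_mm <= 0) stop("protocol_config: 'interval_mm' must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("protocol_config: 'alpha' must be in (0, 1)", call. = FALSE)
  if (max_gap_mm <= 0) stop("protocol_config: 'max_gap_mm' must be > 0", call. = FALSE)
  structure(list(n_slices = as.integer(n_slices), interval_mm = interval_mm,
                 alpha = alpha, bone_threshold = bone_threshold,
                 max_gap_mm = max_gap_mm, n_raters = as.integer(n_raters),
                 n_repeats = as.integer(n_repeats),
                 frame_offset_mm = frame_offset_mm),
            class = "protocol_config")
}

#' Threshold a slice into a bone mask
#'
#' A pixel is bone iff its intensity is `>= threshold`. With
#' `threshold = "auto"` the threshold is the midpoint between the mean
#' intensities of the two classes of a two-class histogram split (the
#' split maximizing the between-class variance); CBCT grey values are not
#' Hounsfield-calibrated, so no absolute default is meaningful.
#'
#' @param s A `slice2d` from [extract_coronal_slice()].
#' @param threshold Numeric intensity, or `"auto"`.
#' @return Logical matrix of the slice's dimensions.
#' @export
bone_mask <- function(s, threshold = "auto") {
  stopifnot(inherits(s, "slice2d"))
  px <- s$pixels
  if (identical(threshold, "auto"))
    threshold <- auto_threshold(px)
  else if (!is.numeric(threshold) || length(threshold) != 1L)
    stop("bone_mask: 'threshold' must be a single number or \"auto\"",
         call. = FALSE)
  px >= threshold
}

# two-class histogram split: exhaustive search for the cut maximizing
# between-class variance, then the midpoint between the two class means
auto_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (!is.finite(diff(rng)) || diff(rng) < .Machine$double.eps * 100)
    stop("auto threshold: degenerate histogram (constant slice)", call. = FALSE)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- h / sum(h)
  mu <- w * mids
  cw <- cumsum(w); cm <- cumsum(mu); mT <- cm[n_bins]
  valid <- cw > 0 & cw < 1
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- (mT * cw[valid] - cm[valid])^2 / (cw[valid] * (1 - cw[valid]))
  k <- which.max(bcv)
  m1 <- cm[k] / cw[k]
  m2 <- (mT - cm[k]) / (1 - cw[k])
  (m1 + m2) / 2
}

#' Close the bony boundary around a seed point
#'
#' Traces the inner boundary of the bony ring enclosing `roi_center` by
#' casting `n_rays` radial rays from the seed and locating, along each
#' ray, the first pixel belonging to a wall-scale bone component (the hit
#' radius is refined by bisection to sub-pixel precision, placing the
#' contour on the cavity/bone interface). Wherever the ring is interrupted
#' (foramina, fissures), the nearest boundary points flanking the
#' interruption are connected with a straight chord, provided the chord is
#' no longer than `max_gap_mm`; otherwise an "unclosable contour" error
#' names the gap size. Bone components visible over less than
#' `min_span_deg` of the view from the seed (noise specks, an implanted
#' sphere) are ignored as non-enclosing.
#'
#' @param mask Logical bone mask (from [bone_mask()]).
#' @param roi_center Seed in pixel coordinates (possibly fractional),
#'   inside the intended cavity.
#' @param max_gap_mm Largest bridgeable interruption in mm.
#' @param pixel_spacing Pixel edge lengths in mm (length 2).
#' @param n_rays Angular sampling of the boundary trace.
#' @param max_radius_mm Search radius around the seed.
#' @param min_span_deg Minimum angular span for a bone component to count
#'   as part of the enclosing wall.
#' @return A list with `contour` (closed polygon, n_rays x 2, pixel
#'   coordinates; closes implicitly), `bridged_segments` (list of chords,
#'   each with pixel-coordinate `from`, `to` and `length_mm`).
#' @export
close_boundary <- function(mask, roi_center, max_gap_mm = 10,
                           pixel_spacing = c(1, 1), n_rays = 720L,
                           max_radius_mm = 30, min_span_deg = 120) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("close_boundary: 'mask' must be a logical matrix", call. = FALSE)
  if (!any(mask))
    stop("close_boundary: no enclosing bone found (empty mask)", call. = FALSE)
  nx <- nrow(mask); ny <- ncol(mask)
  cx <- roi_center[1]; cy <- roi_center[2]
  if (cx < 1 || cx > nx || cy < 1 || cy > ny)
    stop("close_boundary: 'roi_center' outside the slice", call. = FALSE)
  if (isTRUE(mask[round(cx), round(cy)]))
    stop("close_boundary: 'roi_center' lies on bone, not inside a cavity",
         call. = FALSE)

  comp <- round(EBImage::bwlabel(mask))
  sx <- pixel_spacing[1]; sy <- pixel_spacing[2]

  theta <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  step <- 0.5 * min(pixel_spacing)
  radii <- seq(step, max_radius_mm, by = step)
  ux <- cos(theta); uy <- sin(theta)

  # sample the component label field along all rays (mm -> pixel coords)
  sample_comp <- function(r, m_ux, m_uy) {
    ix <- round(cx + (r * m_ux) / sx)
    iy <- round(cy + (r * m_uy) / sy)
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    out <- integer(length(ix))
    out[ok] <- comp[cbind(ix[ok], iy[ok])]
    out
  }
  lab <- matrix(0L, length(radii), n_rays)
  for (si in seq_along(radii))
    lab[si, ] <- sample_comp(radii[si], ux, uy)

  # angular span (in rays) of each component as seen from the seed
  seen <- lab > 0L
  if (!any(seen))
    stop("close_boundary: no enclosing bone found within ", max_radius_mm,
         " mm of the seed", call. = FALSE)
  span <- vapply(seq_len(max(lab)), function(cid)
    sum(colSums(lab == cid) > 0L), integer(1))
  keep <- which(span >= min_span_deg / 360 * n_rays)
  if (!length(keep))
    stop("close_boundary: no enclosing bone found (no bone component ",
         "spans >= ", min_span_deg, " degrees around the seed)", call. = FALSE)

  kept <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  first_hit <- apply(kept, 2, function(col) {
    i <- which(col)
    if (length(i)) i[1] else NA_integer_
  })

  r_hit <- rep(NA_real_, n_rays)
  hit <- !is.na(first_hit)
  if (!any(hit))
    stop("close_boundary: no enclosing bone found around the seed", call. = FALSE)
  for (m in which(hit)) {
    hi <- radii[first_hit[m]]
    lo <- hi - step
    # bisect to the cavity/bone pixel interface
    for (it in 1:12) {
      mid <- (lo + hi) / 2
      if (sample_comp(mid, ux[m], uy[m]) %in% keep) hi <- mid else lo <- mid
    }
    r_hit[m] <- (lo + hi) / 2
  }

  bridged <- list()
  if (any(!hit)) {
    # maximal circular runs of missed rays; bridge each with a chord
    runs <- missing_runs(hit)
    for (run in runs) {
      before <- (run[1] - 2) %% n_rays + 1
      after <- run[length(run)] %% n_rays + 1
      p1 <- c(r_hit[before] * ux[before], r_hit[before] * uy[before])
      p2 <- c(r_hit[after] * ux[after], r_hit[after] * uy[after])
      len <- sqrt(sum((p2 - p1)^2))
      if (len > max_gap_mm)
        stop(sprintf(
          "close_boundary: unclosable contour: gap of %.1f mm exceeds max_gap_mm = %.1f mm",
          len, max_gap_mm), call. = FALSE)
      for (m in run) {
        ri <- ray_segment_intersection(ux[m], uy[m], p1, p2)
        r_hit[m] <- if (is.na(ri)) (r_hit[before] + r_hit[after]) / 2 else ri
      }
      bridged[[length(bridged) + 1L]] <- list(
        from = c(cx + p1[1] / sx, cy + p1[2] / sy),
        to = c(cx + p2[1] / sx, cy + p2[2] / sy),
        length_mm = len)
    }
  }

  contour <- cbind(cx + (r_hit * ux) / sx, cy + (r_hit * uy) / sy)
  colnames(contour) <- c("i", "j")
  list(contour = contour, bridged_segments = bridged)
}

# maximal circular runs of FALSE entries in a logical vector
missing_runs <- function(hit) {
  n <- length(hit)
  miss <- which(!hit)
  if (!length(miss)) return(list())
  # rotate so that position 1 is a hit, then split consecutive misses
  start <- which(hit)[1]
  idx <- ((seq_len(n) + start - 2) %% n) + 1
  runs <- list(); cur <- integer()
  for (i in idx) {
    if (!hit[i]) cur <- c(cur, i)
    else if (length(cur)) { runs[[length(runs) + 1L]] <- cur; cur <- integer() }
  }
  if (length(cur)) runs[[length(runs) + 1L]] <- cur
  runs
}

# distance along the ray (direction u, from the origin) to segment p1-p2
ray_segment_intersection <- function(ux, uy, p1, p2) {
  dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
  den <- ux * dy - uy * dx
  if (abs(den) < 1e-12) return(NA_real_)
  s <- (p1[1] * uy - p1[2] * ux) / den   # position along the segment
  r <- if (abs(ux) > abs(uy)) (p1[1] + s * dx) / ux else (p1[2] + s * dy) / uy
  if (s < -1e-9 || s > 1 + 1e-9 || r <= 0) return(NA_real_)
  r
}

#' Fill a closed contour and measure its area
#'
#' Rasterizes the closed contour onto the pixel grid: a pixel belongs to
#' the region iff its centre is inside or on the contour. The area is
#' exactly the filled pixel count times the pixel area, with no smoothing
#' correction.
#'
#' @param contour n x 2 matrix of pixel coordinates (closed implicitly
#'   from the last vertex to the first). A degenerate single-point contour
#'   fills one pixel.
#' @param pixel_spacing Pixel edge lengths in mm (length 2).
#' @param dim Dimensions `c(nx, ny)` of the target pixel grid.
#' @return List with `filled_mask` (logical matrix) and `area_mm2`.
#' @export
fill_and_measure <- function(contour, pixel_spacing, dim) {
  if (is.null(dim(contour))) contour <- matrix(contour, ncol = 2)
  if (ncol(contour) != 2L || anyNA(contour))
    stop("fill_and_measure: contour must be an n x 2 matrix without NAs ",
         "(non-closed or degenerate contour)", call. = FALSE)
  nx <- as.integer(dim[1]); ny <- as.integer(dim[2])
  uniq <- unique(round(contour, 9))
  if (nrow(uniq) < 3L) {
    filled <- matrix(FALSE, nx, ny)
    i <- round(uniq[1, 1]); j <- round(uniq[1, 2])
    if (i >= 1 && i <= nx && j >= 1 && j <= ny) filled[i, j] <- TRUE
  } else {
    filled <- fill_polygon_cpp(nx, ny, contour[, 1], contour[, 2])
  }
  list(filled_mask = filled,
       area_mm2 = sum(filled) * pixel_spacing[1] * pixel_spacing[2])
}

#' Cavalieri volume estimate
#'
#' Estimates a volume from parallel cross-section areas as
#' `interval_mm * sum(areas)` (Cavalieri principle).
#'
#' @param areas Cross-section areas in mm^2 (>= 0).
#' @param interval_mm Spacing between sections in mm (> 0).
#' @return Volume in mm^3.
#' @export
estimate_volume <- function(areas, interval_mm) {
  if (!length(areas)) stop("estimate_volume: need at least one area", call. = FALSE)
  if (any(areas < 0)) stop("estimate_volume: negative area", call. = FALSE)
  if (interval_mm <= 0) stop("estimate_volume: 'interval_mm' must be > 0", call. = FALSE)
  interval_mm * sum(areas)
}

#' Measure one orbit by serial coronal slices
#'
#' Runs the full per-orbit protocol on a canonically aligned volume: for
#' slice k = 1..n_slices, extracts the coronal plane at
#' `frame_offset_mm - (k - 1) * interval_mm` (dorsal of the orbital frame
#' plane y = 0), thresholds bone, closes the bony boundary around the seed
#' (bridging fissures with chords), flood-fills and measures the area. The
#' seed is re-centred on the previous slice's filled-region centroid
#' before each deeper slice, following the cavity as it drifts toward the
#' apex. The orbital volume is the Cavalieri sum `interval_mm * sum(areas)`.
#'
#' If a slice cannot be closed, a condition of class
#' `orbitovol_partial_measurement` is raised carrying the completed
#' slices in its `$slices` field.
#'
#' @param vol A canonically aligned [volume_image()].
#' @param side `"left"` or `"right"` (label recorded in the result).
#' @param seed_point World point (mm) inside the cavity at the frame plane.
#' @param cfg A [protocol_config()].
#' @return An object of class `orbit_measurement`: list with `side`,
#'   `slices` (per-slice lists: `slice_index`, `plane_position`, `contour`,
#'   `bridged_segments`, `filled_mask`, `area_mm2`) and `volume_mm3`.
#' @export
measure_orbit <- function(vol, side = c("left", "right"), seed_point,
                          cfg = protocol_config()) {
  stopifnot(inherits(vol, "volume_image"), inherits(cfg, "protocol_config"))
  side <- match.arg(side)
  seed_point <- as.numeric(seed_point)
  stopifnot(length(seed_point) == 3L)

  slices <- vector("list", cfg$n_slices)
  seed_xz <- seed_point[c(1, 3)]
  for (k in seq_len(cfg$n_slices)) {
    y_k <- cfg$frame_offset_mm - (k - 1) * cfg$interval_mm
    res <- tryCatch({
      s <- extract_coronal_slice(vol, y_k)
      msk <- bone_mask(s, cfg$bone_threshold)
      seed_px <- c((seed_xz[1] - s$origin[1]) / s$pixel_spacing[1] + 1,
                   (seed_xz[2] - s$origin[2]) / s$pixel_spacing[2] + 1)
      cb <- close_boundary(msk, seed_px, max_gap_mm = cfg$max_gap_mm,
                           pixel_spacing = s$pixel_spacing)
      fm <- fill_and_measure(cb$contour, s$pixel_spacing, dim(msk))
      list(slice_index = k, plane_position = s$plane_position,
           contour = cb$contour, bridged_segments = cb$bridged_segments,
           filled_mask = fm$filled_mask, area_mm2 = fm$area_mm2,
           slice = s)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      done <- slices[seq_len(k - 1)]
      cond <- structure(
        class = c("orbitovol_partial_measurement", "error", "condition"),
        list(message = paste0("measure_orbit: slice ", k, " failed: ",
                              conditionMessage(res)),
             call = sys.call(-1), slices = done))
      stop(cond)
    }
    # re-centre the seed on this slice's filled-region centroid (mm)
    idx <- which(res$filled_mask, arr.ind = TRUE)
    s <- res$slice
    seed_xz <- c(s$origin[1] + (mean(idx[, 1]) - 1) * s$pixel_spacing[1],
                 s$origin[2] + (mean(idx[, 2]) - 1) * s$pixel_spacing[2])
    res$slice <- NULL
    slices[[k]] <- res
  }
  areas <- vapply(slices, `[[`, numeric(1), "area_mm2")
  structure(list(side = side, slices = slices,
                 volume_mm3 = estimate_volume(areas, cfg$interval_mm)),
            class = "orbit_measurement")
}

#' @export
print.orbit_measurement <- function(x, ...) {
  cat("orbit_measurement (", x$side, " orbit)\n", sep = "")
  df <- measurement_table(x)
  print(df, row.names = FALSE)
  cat("Cavalieri volume:", format(x$volume_mm3, digits = 7), "mm^3\n")
  invisible(x)
}

#' Per-slice area table of a measurement
#'
#' @param m An `orbit_measurement`.
#' @return A data frame with columns `side`, `slice_index`,
#'   `plane_position_mm`, `area_mm2`, `n_bridged_gaps`.
#' @export
measurement_table <- function(m) {
  stopifnot(inherits(m, "orbit_measurement"))
  data.frame(
    side = m$side,
    slice_index = vapply(m$slices, `[[`, numeric(1), "slice_index"),
    plane_position_mm = vapply(m$slices, `[[`, numeric(1), "plane_position"),
    area_mm2 = vapply(m$slices, `[[`, numeric(1), "area_mm2"),
    n_bridged_gaps = vapply(m$slices, function(s)
      length(s$bridged_segments), numeric(1)))
}
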