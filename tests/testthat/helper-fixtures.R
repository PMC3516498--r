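# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, build(), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# small single-scale phantom for fast unit tests: bilateral 16 x 14 mm rims,
# 18 mm deep, 0.4 mm voxels
small_phantom_spec <- function(noise_sd = 0, gaps = FALSE, rng_seed = 1L) {
  gap_r <- if (gaps) list(list(depth_range = c(2, 12), angle_deg = -40,
                               width_mm = 2)) else list()
  gap_l <- lapply(gap_r, function(g) { g$angle_deg <- 180 - g$angle_deg; g })
  phantom_spec(
    left = orbit_spec(16, 14, 18, rim_center = c(-13, 0, 0), gap_specs = gap_l),
    right = orbit_spec(16, 14, 18, rim_center = c(13, 0, 0), gap_specs = gap_r),
    voxel_spacing = 0.4, wall_thickness = 1.6, margin_mm = 3,
    noise_sd = noise_sd, rng_seed = rng_seed)
}

small_cfg <- function(...) protocol_config(n_slices = 3L, interval_mm = 3, ...)

small_phantom <- function() cached("small", function()
  generate_phantom(small_phantom_spec()))

small_phantom_noisy <- function() cached("small_noisy", function()
  generate_phantom(small_phantom_spec(noise_sd = 50)))

default_phantom <- function() cached("default", function()
  generate_phantom(default_phantom_spec()))

default_phantom_noiseless <- function() cached("default_nonoise", function()
  generate_phantom(default_phantom_spec(noise_sd = 0)))

default_phantom_noiseless_nogap <- function() cached("default_nonoise_nogap",
  function() generate_phantom(default_phantom_spec(noise_sd = 0, gaps = FALSE)))

default_right_measurement <- function() cached("default_meas_r", function()
  measure_orbit(default_phantom()$volume, "right", c(32, 0, 0)))

default_left_measurement <- function() cached("default_meas_l", function()
  measure_orbit(default_phantom()$volume, "left", c(-32, 0, 0)))

# annular bone mask on an n x n pixel grid (pixel units; spacing in mm),
# optionally with an angular sector gap; independent of close_boundary
ring_mask <- function(n = 101, sp = 0.3, center = c(51, 51), r0 = 10, w = 2,
                      gap_deg = NULL, gap_at = 0) {
  ii <- matrix(seq_len(n), n, n)
  jj <- matrix(seq_len(n), n, n, byrow = TRUE)
  dx <- (ii - center[1]) * sp
  dy <- (jj - center[2]) * sp
  r <- sqrt(dx^2 + dy^2)
  m <- r >= r0 & r <= r0 + w
  if (!is.null(gap_deg)) {
    ang <- atan2(dy, dx) * 180 / pi
    d <- abs(((ang - gap_at + 180) %% 360) - 180)
    m <- m & d > gap_deg / 2
  }
  m
}

table1_patterns <- function() read_slice_flags(
  system.file("extdata", "implant_cohort_slice_flags.csv", package = "orbitovol"))
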