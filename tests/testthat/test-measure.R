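test_that("bone_mask reproduces the noiseless bone labels and tolerates
           default noise under the auto threshold", {
  s0 <- extract_coronal_slice(small_phantom()$volume, -3)
  m0 <- bone_mask(s0, "auto")
  expect_identical(m0, s0$pixels == 1000)      # noiseless: exact construction
  sn <- extract_coronal_slice(small_phantom_noisy()$volume, -3)
  mn <- bone_mask(sn, "auto")
  expect_gte(mean(mn == m0), 0.99)
  # explicit numeric threshold
  expect_identical(bone_mask(s0, 500), s0$pixels >= 500)
  const <- structure(list(pixels = matrix(1, 5, 5), pixel_spacing = c(1, 1),
                          origin = c(0, 0), plane_position = 0,
                          plane_axis = "posterior-anterior"),
                     class = "slice2d")
  expect_error(bone_mask(const, "auto"), "degenerate histogram")
})

test_that("close_boundary traces a complete ring without bridging", {
  m <- ring_mask()
  cb <- close_boundary(m, c(51, 51), pixel_spacing = c(0.3, 0.3))
  expect_length(cb$bridged_segments, 0)
  r <- sqrt(rowSums(sweep(cb$contour, 2, c(51, 51))^2)) * 0.3
  # contour sits on the inner boundary of the ring (within half a pixel)
  expect_true(all(abs(r - 10) <= 0.3))
})

test_that("close_boundary bridges a sector gap with a single chord and the
           enclosed area barely changes", {
  m0 <- ring_mask()
  m4 <- ring_mask(gap_deg = 4 / 10 * 180 / pi)  # 4 mm arc at 10 mm radius
  cb0 <- close_boundary(m0, c(51, 51), pixel_spacing = c(0.3, 0.3))
  cb4 <- close_boundary(m4, c(51, 51), pixel_spacing = c(0.3, 0.3))
  expect_length(cb4$bridged_segments, 1)
  len <- cb4$bridged_segments[[1]]$length_mm
  expect_lt(abs(len - 4), 0.3 * sqrt(2) + 1e-9)  # within one pixel diagonal
  a0 <- fill_and_measure(cb0$contour, c(0.3, 0.3), dim(m0))$area_mm2
  a4 <- fill_and_measure(cb4$contour, c(0.3, 0.3), dim(m4))$area_mm2
  expect_lt(abs(a4 - a0) / a0, 0.005)
})

test_that("close_boundary refuses gaps beyond max_gap_mm and seeds outside
           a cavity", {
  m15 <- ring_mask(gap_deg = 15 / 10 * 180 / pi)
  expect_error(close_boundary(m15, c(51, 51), max_gap_mm = 10,
                              pixel_spacing = c(0.3, 0.3)),
               "unclosable contour.*exceeds max_gap_mm")
  m <- ring_mask()
  expect_error(close_boundary(m, c(51, 85), pixel_spacing = c(0.3, 0.3)),
               "on bone")
  expect_error(close_boundary(matrix(FALSE, 9, 9), c(5, 5)), "no enclosing bone")
})

test_that("interior bone islands (implants) are ignored by the angular-span
           filter", {
  m <- ring_mask()
  # 3 mm-radius island centred 5 mm from the seed
  isl <- ring_mask(r0 = 0, w = 3, center = c(51 + 5 / 0.3, 51))
  cb <- close_boundary(m | isl, c(51, 51), pixel_spacing = c(0.3, 0.3))
  r <- sqrt(rowSums(sweep(cb$contour, 2, c(51, 51))^2)) * 0.3
  expect_true(all(abs(r - 10) <= 0.3))   # contour still on the outer ring
})

test_that("fill_and_measure matches a brute-force point-in-polygon count
           exactly and area is pixel count times pixel area", {
  n <- 101; sp <- 0.3; cx <- 51.17; cy <- 50.83
  th <- 2 * pi * (0:719) / 720
  poly <- cbind(cx + 10 * cos(th) / sp, cy + 10 * sin(th) / sp)
  fm <- fill_and_measure(poly, c(sp, sp), c(n, n))
  # independent oracle: count pixel centres inside the disc
  oracle <- sum(outer(1:n, 1:n, function(i, j)
    ((i - cx) * sp)^2 + ((j - cy) * sp)^2 <= 100))
  expect_identical(sum(fm$filled_mask), oracle)
  expect_equal(fm$area_mm2, sum(fm$filled_mask) * sp^2)
  expect_lt(abs(fm$area_mm2 - pi * 100) / (pi * 100), 0.01)
})

test_that("degenerate single-point contours fill exactly one pixel", {
  fm <- fill_and_measure(matrix(c(5, 5), 1, 2), c(0.3, 0.3), c(9, 9))
  expect_equal(sum(fm$filled_mask), 1)
  expect_equal(fm$area_mm2, 0.09)
  expect_error(fill_and_measure(matrix(NA_real_, 2, 2), c(1, 1), c(5, 5)),
               "contour")
})

test_that("the Cavalieri estimator is interval times the area sum", {
  expect_equal(estimate_volume(c(100, 80, 60, 40, 20), 4.8), 1440)
  expect_equal(estimate_volume(123.4, 4.8), 4.8 * 123.4)
  expect_equal(estimate_volume(c(0, 0, 0), 4.8), 0)
  expect_error(estimate_volume(c(10, -1), 4.8), "negative")
  expect_error(estimate_volume(numeric(0), 4.8), "at least one")
  expect_error(estimate_volume(10, 0), "> 0")
})

test_that("measure_orbit recovers analytic slice areas on the small phantom
           with strictly decreasing areas and the exact Cavalieri sum", {
  ph <- small_phantom()
  m <- measure_orbit(ph$volume, "right", c(13, 0, 0), small_cfg())
  tb <- measurement_table(m)
  aa <- analytic_area(ph$truth, "right", c(0, 3, 6))
  expect_true(all(abs(tb$area_mm2 - aa) / aa < 0.02))
  expect_true(all(diff(tb$area_mm2) < 0))     # cone: monotone decreasing
  expect_equal(m$volume_mm3, 3 * sum(tb$area_mm2))
  expect_identical(m$side, "right")
})

test_that("fissure-scale gap openings change adult-scale slice areas by
           well under one percent", {
  mg <- measure_orbit(default_phantom_noiseless()$volume, "right", c(32, 0, 0))
  m0 <- measure_orbit(default_phantom_noiseless_nogap()$volume, "right",
                      c(32, 0, 0))
  ag <- measurement_table(mg)$area_mm2
  a0 <- measurement_table(m0)$area_mm2
  expect_true(all(abs(ag - a0) / a0 < 0.01))
  expect_gte(sum(measurement_table(mg)$n_bridged_gaps), 1)
})

test_that("an unmeasurable deep slice raises a partial-result condition
           carrying the completed slices", {
  ph <- small_phantom()
  cfg <- protocol_config(n_slices = 4L, interval_mm = 8)  # slice 4 beyond apex
  err <- tryCatch(measure_orbit(ph$volume, "right", c(13, 0, 0), cfg),
                  orbitovol_partial_measurement = function(e) e)
  expect_s3_class(err, "orbitovol_partial_measurement")
  expect_gte(length(err$slices), 1)
  expect_true(all(vapply(err$slices, function(s) s$area_mm2 > 0, logical(1))))
})

test_that("measured areas obey the square scaling law under uniform shrink", {
  spec <- small_phantom_spec()
  sh <- make_asymmetric_pair(spec, 0.1, side = "left")
  ph <- generate_phantom(sh)
  cfg <- small_cfg()
  ml <- measure_orbit(ph$volume, "left", c(-13, 0, 0), cfg)
  mr <- measure_orbit(ph$volume, "right", c(13, 0, 0), cfg)
  a_l1 <- measurement_table(ml)$area_mm2[1]
  a_r1 <- measurement_table(mr)$area_mm2[1]
  expect_lt(abs(a_l1 / a_r1 - 0.81), 0.02)
})
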