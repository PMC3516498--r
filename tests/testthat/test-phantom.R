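test_that("analytic cross-section areas follow the cone law", {
  gt <- generate_phantom(small_phantom_spec())$truth
  # adult-scale closed forms, independent of the small fixture
  gt40 <- structure(list(spec = default_phantom_spec(noise_sd = 0)),
                    class = "ground_truth")
  expect_equal(analytic_area(gt40, "right", 0), pi * 20 * 17.5,
               tolerance = 1e-12)
  expect_equal(analytic_area(gt40, "right", 45), 0)
  expect_equal(analytic_area(gt40, "right", 22.5), pi * 20 * 17.5 / 4,
               tolerance = 1e-12)
  expect_error(analytic_area(gt40, "right", 46), "outside")
  # rim-area value cross-checked by rasterization count at 0.05 mm pixels
  g <- seq(-20.025, 20.025, by = 0.05)
  inside <- outer(g, g, function(x, z) (x / 20)^2 + (z / 17.5)^2 <= 1)
  expect_equal(sum(inside) * 0.05^2, analytic_area(gt40, "right", 0),
               tolerance = 2e-3)
  expect_error(analytic_area(gt, "left", -1), "outside")
})

test_that("analytic volume equals the quadrature of the analytic area", {
  gt <- generate_phantom(small_phantom_spec())$truth
  for (iv in list(c(0, 18), c(2.5, 11), c(-1.5, 7.25))) {
    q <- stats::integrate(function(u)
      vapply(u, function(ui)
        if (ui < 0)  # extrapolated cone law ventral of the rim
          pi * 8 * 7 * (1 - ui / 18)^2
        else analytic_area(gt, "right", ui), numeric(1)),
      iv[1], iv[2], rel.tol = 1e-8)$value
    expect_equal(analytic_volume(gt, "right", iv[1], iv[2]), q,
                 tolerance = 1e-3)
  }
})

test_that("voxelized cavity volume matches the closed-form cone volume", {
  # gapless, noiseless, adult-scale: count cavity voxels behind the rim
  ph <- default_phantom_noiseless_nogap()
  v <- ph$volume
  jrim <- round((0 - v$origin[2]) / v$spacing[2]) + 1
  n_cavity <- sum(v$voxels[, seq_len(jrim), ] == 100)
  vox_vol <- n_cavity * prod(v$spacing)
  analytic <- (1 / 3) * pi * 20 * 17.5 * 45 * 2   # both orbits
  expect_lt(abs(vox_vol - analytic) / analytic, 0.01)
})

test_that("noiseless gapless phantoms contain exactly three intensities and
           are deterministic under a fixed seed", {
  ph <- generate_phantom(small_phantom_spec(noise_sd = 0))
  expect_length(unique(as.vector(ph$volume$voxels)), 3L)
  s1 <- generate_phantom(small_phantom_spec(noise_sd = 30, rng_seed = 9L))
  s2 <- generate_phantom(small_phantom_spec(noise_sd = 30, rng_seed = 9L))
  expect_identical(s1$volume$voxels, s2$volume$voxels)
  s3 <- generate_phantom(small_phantom_spec(noise_sd = 30, rng_seed = 10L))
  expect_false(identical(s1$volume$voxels, s3$volume$voxels))
})

test_that("noiseless symmetric phantoms are bit-exactly mirror symmetric", {
  v <- default_phantom_noiseless()$volume$voxels
  expect_identical(v, v[dim(v)[1]:1, , ])
})

test_that("make_asymmetric_pair scales one side by (1 - s) and leaves the
           other untouched", {
  spec <- small_phantom_spec()
  expect_identical(make_asymmetric_pair(spec, 0), spec)
  sh <- make_asymmetric_pair(spec, 0.1, side = "left")
  gt0 <- structure(list(spec = spec), class = "ground_truth")
  gt1 <- structure(list(spec = sh), class = "ground_truth")
  expect_equal(analytic_volume(gt1, "left", 0, sh$left$depth),
               0.9^3 * analytic_volume(gt0, "left", 0, spec$left$depth),
               tolerance = 1e-10)
  expect_equal(analytic_area(gt1, "left", 0), 0.9^2 * analytic_area(gt0, "left", 0),
               tolerance = 1e-10)
  expect_identical(sh$right, spec$right)
  expect_error(make_asymmetric_pair(spec, 1), "shrink_fraction")
})

test_that("overlapping cavities and invalid specs are rejected", {
  expect_error(generate_phantom(phantom_spec(
    orbit_spec(rim_center = c(-10, 0, 0)), orbit_spec(rim_center = c(10, 0, 0)))),
    "overlap")
  expect_error(orbit_spec(rim_width = 0), "> 0")
  expect_error(phantom_spec(orbit_spec(rim_center = c(-32, 0, 0)),
                            orbit_spec(rim_center = c(32, 0, 0)),
                            noise_sd = 300), "5 \\* noise_sd")
  expect_error(orbit_spec(implant = list(center = c(0, -5, 0), diameter = 40)),
               "inside the cavity")
})

test_that("phantom spec JSON round-trips", {
  spec <- default_phantom_spec()
  f <- tempfile(fileext = ".json")
  write_phantom_spec(spec, f)
  spec2 <- read_phantom_spec(f)
  expect_equal(spec2$right$rim_width, spec$right$rim_width)
  expect_equal(spec2$voxel_spacing, spec$voxel_spacing)
  expect_equal(length(spec2$right$gap_specs), length(spec$right$gap_specs))
  expect_equal(spec2$right$gap_specs[[1]]$width_mm,
               spec$right$gap_specs[[1]]$width_mm)
})
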