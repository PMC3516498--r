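test_that("paired_t matches the closed-form reference", {
  tt <- paired_t(c(1, 2, 4), c(2, 3, 4))
  expect_equal(tt$statistic, -2, tolerance = 1e-12)
  expect_equal(tt$df, 2)
  # closed-form p for df = 2: p = 1 - |t| / sqrt(2 + t^2)
  expect_equal(tt$p_value, 1 - 2 / sqrt(2 + 4), tolerance = 1e-10)

  # brute-force oracle on random inputs: direct formula + t distribution
  set.seed(42)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    a <- rnorm(n, 50, 5); b <- rnorm(n, 49, 5)
    d <- a - b
    t_ref <- mean(d) / (sd(d) / sqrt(n))
    p_ref <- 2 * pt(-abs(t_ref), n - 1)
    tt <- paired_t(a, b)
    expect_equal(tt$statistic, t_ref, tolerance = 1e-10)
    expect_equal(tt$p_value, p_ref, tolerance = 1e-10)
    # shift invariance: adding a constant to both members changes nothing
    ts <- paired_t(a + 13.7, b + 13.7)
    expect_equal(ts$statistic, tt$statistic, tolerance = 1e-9)
    expect_equal(ts$p_value, tt$p_value, tolerance = 1e-9)
  }
})

test_that("degenerate differences are rejected (or yield t = 0 only on
           request)", {
  a <- c(3, 5, 8)
  expect_error(paired_t(a, a), "all differences are zero")
  expect_error(paired_t(a + 2, a), "degenerate variance")
  z <- paired_t(a, a, zero_diff = "zero")
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  expect_error(paired_t(1, 2), "at least 2")
  expect_error(paired_t(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("slice_significance flags slices where the operated orbit is
           significantly smaller, one-directionally", {
  cfg <- protocol_config()
  healthy <- c(1100, 880, 680, 510, 360)
  set.seed(1)
  # operated shifted down 10 mm^2, rater noise sd ~1 mm^2 (9 pairs): strong
  rm <- simulate_repeated_measures(healthy - 10, healthy,
                                   noise_sd = 1 / mean(healthy))
  pat <- slice_significance(rm, cfg)
  expect_true(all(pat$flags))
  expect_true(all(pat$p_values < 0.001))

  # operated larger: two-sided p may be small but the flag must stay FALSE
  set.seed(2)
  rm2 <- simulate_repeated_measures(healthy + 50, healthy, noise_sd = 0.002)
  pat2 <- slice_significance(rm2, cfg)
  expect_true(all(pat2$p_values < 0.05))
  expect_false(any(pat2$flags))
})

test_that("repeated_measures validates completeness and side labels", {
  df <- expand.grid(replicate = 1:2, rater = 1:2, slice_index = 1:2,
                    side = c("left", "right"), stringsAsFactors = FALSE)
  df$case_id <- "c1"; df$area_mm2 <- 100
  expect_s3_class(repeated_measures(df), "repeated_measures")
  expect_error(repeated_measures(df[-1, ]), "both sides")
  df2 <- df; df2$side[1] <- "up"
  expect_error(repeated_measures(df2), "side")
  df3 <- df; df3$area_mm2[1] <- -5
  expect_error(repeated_measures(df3), ">= 0")
})

test_that("every 5-slice pattern maps to exactly one category and the
           published examples classify correctly", {
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), 5))
  for (i in seq_len(nrow(grid))) {
    f <- as.logical(grid[i, ])
    cc <- classify_case(slice_pattern("x", f))
    # independent re-derivation of the rule
    expected <- if (all(f[1:4])) "A" else if (!any(f)) "C" else "B"
    expect_identical(cc$category, expected)
    expect_equal(cc$n_significant, sum(f))
    expect_identical(cc$atypical, expected == "B" && sum(f) >= 4)
  }
  expect_identical(classify_case(slice_pattern(2, c(T, T, T, T, F)))$category, "A")
  p9 <- classify_case(slice_pattern(9, c(F, T, T, F, T)))
  expect_identical(p9$category, "B")
  expect_equal(p9$n_significant, 3)
  expect_identical(classify_case(slice_pattern(6, rep(FALSE, 5)))$category, "C")
})

test_that("cohort summaries count categories, are permutation invariant,
           and reject empty cohorts", {
  pats <- table1_patterns()
  s <- summarize_cohort(pats)
  expect_equal(c(s$count_A, s$count_B, s$count_C), c(5, 12, 3))
  expect_equal(s$n_cases, 20)
  set.seed(5)
  s2 <- summarize_cohort(sample(pats))
  expect_equal(s2[c("count_A", "count_B", "count_C")],
               s[c("count_A", "count_B", "count_C")])
  # idealized control group: all patterns empty
  ctrl <- summarize_cohort(lapply(1:20, function(i)
    slice_pattern(i, rep(FALSE, 5))))
  expect_equal(c(ctrl$count_A, ctrl$count_B, ctrl$count_C), c(0, 0, 20))
  expect_error(summarize_cohort(list()), "empty")
})

test_that("rater reproducibility CVs recover constructed variance
           components", {
  base <- expand.grid(replicate = 1:3, rater = 1:3, slice_index = 1,
                      side = c("left", "right"), stringsAsFactors = FALSE)
  base$case_id <- "c1"
  # all nine values identical -> both CVs zero
  base$area_mm2 <- 100
  cv <- rater_reproducibility(repeated_measures(base))
  expect_true(all(cv$intra_rater_cv == 0))
  expect_true(all(cv$inter_rater_cv == 0))
  # rater means all 100, within-rater sd 1 -> intra 0.01, inter 0
  base$area_mm2 <- 100 + rep(c(-1, 0, 1), times = 6)  # sample sd 1, mean 0
  cv2 <- rater_reproducibility(repeated_measures(base))
  expect_equal(unique(cv2$inter_rater_cv), 0, tolerance = 1e-12)
  expect_equal(unique(cv2$intra_rater_cv), 0.01, tolerance = 1e-12)

  # simulation: known rater bias and repeat noise are recovered on average
  set.seed(8)
  reps <- replicate(300, {
    rm <- simulate_repeated_measures(rep(500, 1), rep(500, 1),
                                     noise_sd = 0.02, rater_sd = 0.05)
    cv <- rater_reproducibility(rm)
    c(intra = mean(cv$intra_rater_cv), inter = mean(cv$inter_rater_cv))
  })
  # sd-of-3 estimates are biased low (c4 correction ~0.886 for n = 3)
  expect_lt(abs(mean(reps["intra", ]) / (0.886 * 0.02) - 1), 0.1)
  expect_lt(abs(mean(reps["inter", ]) / (0.886 * sqrt(0.05^2 + 0.02^2 / 3)) - 1),
            0.1)
  expect_error(rater_reproducibility(repeated_measures(
    transform(base, rater = 1))), ">= 2 raters")
})

test_that("symmetric cases with five uncorrected tests still land in
           category C most of the time", {
  healthy <- c(1100, 880, 680, 510, 360)
  set.seed(31)
  cats <- replicate(200, {
    rm <- simulate_repeated_measures(healthy, healthy, noise_sd = 0.02)
    classify_case(slice_significance(rm, protocol_config()))$category
  })
  expect_gte(mean(cats == "C"), 0.7)
})
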