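test_that("local-polynomial smoothing reproduces polynomials and reduces noise", {
  n <- 1:40
  quad <- 3 + 0.5 * n - 0.02 * n^2
  expect_equal(smooth_curve(quad), quad, tolerance = 1e-9)
  expect_equal(smooth_curve(rep(7, 40)), rep(7, 40))
  ## Monte-Carlo: smoothing a noisy sigmoid shrinks the variance about the
  ## generating curve
  truth <- logistic_curve()
  set.seed(42)
  worse <- 0
  for (k in 1:100) {
    noisy <- truth + rnorm(40, 0, 20)
    if (mean((smooth_curve(noisy) - truth)^2) >= mean((noisy - truth)^2))
      worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("central second difference matches closed forms", {
  n <- 1:20
  expect_equal(second_derivative(2 + 3 * n)[2:19], rep(0, 18))
  expect_equal(second_derivative(n^2)[2:19], rep(2, 18))
  ## exponential: d2(n)/f(n) = E - 2 + 1/E = (E-1)^2/E
  E <- 1.9
  f <- E^n
  ratio <- second_derivative(f)[2:19] / f[2:19]
  expect_equal(ratio, rep((E - 1)^2 / E, 18), tolerance = 1e-12)
  expect_error(second_derivative(c(1, 2)), class = "qpcrcal_short_curve")
})

test_that("baseline correction recovers flat and pre-exponential baselines", {
  flat <- baseline_correct(1:40, rep(100, 40))
  expect_equal(flat$baseline_value, 100)
  expect_equal(flat$f_corr, rep(0, 40))

  f <- ideal_curve(n0 = 1e4, baseline = 50)   # rise begins around cycle 20
  cv <- baseline_correct(1:40, f)
  expect_lt(abs(cv$baseline_value - 50) / 50, 0.01)

  expect_error(baseline_correct(1:5, rep(1, 5)), class = "qpcrcal_short_curve")
  ## probe_region override
  cv2 <- baseline_correct(1:40, f, probe_region = 3:10)
  expect_equal(cv2$baseline_cycles, c(3, 10))
})

test_that("find_sdm matches the dense analytic oracle on logistic curves", {
  for (mid in seq(15, 35, by = 2.5)) {
    for (sl in c(1, 1.5, 2, 2.5, 3)) {
      cv <- baseline_correct(1:50, logistic_curve(50, mid, sl))
      expect_lt(abs(find_sdm(cv) - logistic_sdm_truth(mid, sl)), 0.1,
                label = sprintf("sdm error (mid %.1f, slope %.1f)", mid, sl))
    }
  }
  ## the reference example: midpoint 25, slope 1.5 -> sdm ~ 23.02, in (22, 24)
  cv <- baseline_correct(1:40, logistic_curve(40, 25, 1.5))
  sdm <- find_sdm(cv)
  expect_gt(sdm, 22); expect_lt(sdm, 24)
  ## translation equivariance: +5 cycles shifts the sdm by +5
  cv5 <- baseline_correct(1:40, logistic_curve(40, 30, 1.5))
  expect_lt(abs(find_sdm(cv5) - sdm - 5), 0.05)
  ## flat noise-only series is a non-amplifying error
  set.seed(42)
  noise <- baseline_correct(1:40, rnorm(40, 100, 1))
  expect_error(find_sdm(noise), class = "qpcrcal_no_amplification")
})

test_that("take-off precedes the SDM and respects its threshold definition", {
  cv <- baseline_correct(1:40, logistic_curve(40, 25, 1.5))
  sdm <- find_sdm(cv)
  to <- find_takeoff(cv, sdm = sdm)
  expect_lt(to, sdm)
  expect_lt(cv$f_smooth[round(to)], cv$f_smooth[round(sdm)])
  ## ideal exponential leaving baseline around cycle 20 (plateau bend at
  ## cycle 23): takeoff lands in [19, 22]
  n0_onset20 <- 1e12 / 1.9^23
  cv2 <- baseline_correct(1:40, ideal_curve(n0 = n0_onset20, baseline = 0))
  to2 <- find_takeoff(cv2)
  expect_gte(to2, 19); expect_lte(to2, 22)
  ## fraction -> 1 drives the takeoff to within one cycle of the sdm
  to1 <- find_takeoff(cv, fraction = 1, sdm = sdm)
  expect_lt(sdm - to1, 1)
})

test_that("window selection arithmetic and degenerate handling", {
  w <- select_window(21.4, 26.7)
  expect_equal(c(w$start, w$end, w$n_points), c(22, 26, 5))
  expect_equal(select_window(20.0, 26.7)$start, 20)
  ## a sliver window either widens along a strictly rising smoothed curve or
  ## raises short_window
  cv <- baseline_correct(1:40, ideal_curve(n0 = 1e4, baseline = 0))
  w2 <- select_window(24.9, 25.1, cv)
  expect_equal(c(w2$start, w2$end, w2$n_points), c(25, 27, 3))
  expect_error(select_window(24.9, 25.1), class = "qpcrcal_short_window")
})

test_that("efficiency regression is exact on log-linear data and robust to noise", {
  n <- 1:40
  f <- 0.001 * 1.9^n
  cv <- structure(list(cycles = n, f_raw = f, f_corr = f,
                       f_smooth = smooth_curve(f), baseline_value = 0,
                       baseline_cycles = c(3, 10)), class = "corrected_curve")
  w <- select_window(20, 26.5)
  est <- estimate_efficiency(cv, w)
  expect_equal(est$E, 1.9, tolerance = 1e-9)
  expect_equal(est$r2, 1, tolerance = 1e-12)
  expect_length(est$flags, 0)

  ## a zero-fluorescence cycle inside the window is dropped, not fatal
  f2 <- f; f2[22] <- 0
  cv2 <- cv; cv2$f_corr <- f2
  est2 <- estimate_efficiency(cv2, w)
  expect_equal(est2$n_used, w$n_points - 1L)
  expect_equal(est2$E, 1.9, tolerance = 1e-9)

  ## Monte-Carlo: 2 % multiplicative noise keeps E in [1.85, 1.95] >= 95 %
  set.seed(42)
  hits <- 0
  for (k in 1:500) {
    fn <- f * (1 + rnorm(40, 0, 0.02))
    cvn <- cv; cvn$f_corr <- fn
    E <- estimate_efficiency(cvn, w)$E
    if (E >= 1.85 && E <= 1.95) hits <- hits + 1
  }
  expect_gte(hits / 500, 0.95)
})

test_that("efficiency estimates are flagged, never clamped", {
  n <- 1:40
  f <- 0.001 * 2.3^n      # pathological efficiency
  cv <- structure(list(cycles = n, f_raw = f, f_corr = f,
                       f_smooth = smooth_curve(f), baseline_value = 0,
                       baseline_cycles = c(3, 10)), class = "corrected_curve")
  est <- estimate_efficiency(cv, select_window(20, 24.5))
  expect_equal(est$E, 2.3, tolerance = 1e-9)
  expect_true("e_out_of_range" %in% est$flags)
  est3 <- estimate_efficiency(cv, select_window(20, 22.5))
  expect_true("short_window" %in% est3$flags)
})

test_that("efficiency-mismatch error percentages match the closed form", {
  expect_equal(efficiency_error_pct(1.97, 30, truncate = TRUE), 57)
  expect_equal(efficiency_error_pct(1.90, 30, truncate = TRUE), 365)
  expect_equal(efficiency_error_pct(2.0, 17), 0)
  expect_equal(efficiency_error_pct(1.9, 30), ((2^30 / 1.9^30) - 1) * 100)
})

test_that("landmarks are translation-equivariant and scale-invariant", {
  base <- ideal_curve(n_cycles = 45, n0 = 1e4, baseline = 50)
  an <- analyze_well(1:45, base)
  ## scale invariance: c * F leaves landmarks and E unchanged
  for (c_mult in c(0.2, 5)) {
    an_s <- analyze_well(1:45, base * c_mult)
    expect_equal(an_s$window$takeoff, an$window$takeoff, tolerance = 1e-9)
    expect_equal(an_s$window$sdm, an$window$sdm, tolerance = 1e-9)
    expect_equal(an_s$eff$E, an$eff$E, tolerance = 1e-6)
  }
  ## translation: delaying the onset by k cycles shifts both landmarks by k
  k <- 3
  shifted <- ideal_curve(n_cycles = 45, n0 = 1e4 / 1.9^k, baseline = 50)
  an_t <- analyze_well(1:45, shifted)
  expect_lt(abs(an_t$window$takeoff - an$window$takeoff - k), 0.05)
  expect_lt(abs(an_t$window$sdm - an$window$sdm - k), 0.05)
  expect_equal(an_t$eff$E, an$eff$E, tolerance = 1e-6)
})
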