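test_that("pmol/copies conversions follow Avogadro x 1e-12", {
  expect_equal(pmol_to_copies(1), 6.022e11)
  expect_equal(pmol_to_copies(0), 0)
  expect_equal(signif(pmol_to_copies(7.47e-9), 3), 4.5e3)
  expect_equal(copies_to_pmol(pmol_to_copies(0.37)), 0.37)
})

test_that("an ideal noiseless well is quantified to its true copy number", {
  cfg <- noiseless_cfg(dilution_copies = 1e4, dilution_replicates = 1L)
  sim <- simulate_plate(cfg)
  q <- quantify_plate(sim$run)
  r <- q$results[["A1"]]
  expect_equal(r$mean_copies, 1e4, tolerance = 1e-3 / 100)
  ## back-calculated per-cycle pmz is constant across the window
  expect_lt(sd(r$per_cycle$pmz) / mean(r$per_cycle$pmz), 1e-6)
  expect_equal(r$sem_pmz, r$sd_pmz / sqrt(r$n_retained))
})

test_that("a mis-supplied efficiency biases copies as the closed form predicts", {
  ## true kinetics E = 1.9; quantify pretending E = 2.0: at a window centred
  ## on cycle n the estimate is low by a factor 1 + error_pct(1.9, n)/100
  cfg <- noiseless_cfg(dilution_copies = 4500, dilution_replicates = 1L)
  sim <- simulate_plate(cfg)
  q <- quantify_plate(sim$run)
  r_true <- q$results[["A1"]]
  an <- analyze_well(1:40, sim$run$fluor[, "A1"])
  eff2 <- an$eff; eff2$E <- 2.0
  r2 <- quantify_well(an$curve, eff2, q$calibration)
  expect_lt(r2$mean_copies, r_true$mean_copies)
  n_mid <- mean(r2$per_cycle$cycle)
  predicted <- 1 + efficiency_error_pct(1.9, n_mid) / 100
  expect_equal(r_true$mean_copies / r2$mean_copies, predicted,
               tolerance = 0.02)
})

test_that("cycles mapping to non-positive pmols are dropped", {
  cfg <- noiseless_cfg(dilution_copies = 1e4, dilution_replicates = 1L)
  sim <- simulate_plate(cfg)
  q <- quantify_plate(sim$run)
  an <- analyze_well(1:40, sim$run$fluor[, "A1"])
  ## raise the calibration intercept so the first window cycle back-calculates
  ## to a negative amount
  wider <- an$eff
  wider$window <- select_window(an$window$takeoff - 2, an$window$sdm, an$curve)
  cal <- q$calibration
  cal$b <- mean(an$curve$f_corr[wider$window$start + 0:1])
  r <- quantify_well(an$curve, wider, cal)
  expect_gt(r$n_dropped, 0)
  expect_true("dropped_cycles" %in% r$flags)
  ## too few surviving cycles is a classed error
  cal$b <- an$curve$f_corr[an$window$end] + 1
  expect_error(quantify_well(an$curve, an$eff, cal),
               class = "qpcrcal_cannot_quantify")
  bad <- an$eff; bad$E <- 0.99
  expect_error(quantify_well(an$curve, bad, q$calibration),
               class = "qpcrcal_invalid_efficiency")
})

test_that("replicate aggregation returns per-group mean, SD and SEM", {
  mk <- function(w, grp, copies)
    structure(list(well_id = w, target = "Ar", sample_group = grp,
                   replicate = 1L, E = 1.9, window = NULL,
                   per_cycle = data.frame(), n_retained = 3L, n_dropped = 0L,
                   mean_pmz = copies_to_pmol(copies), sd_pmz = 0, sem_pmz = 0,
                   mean_copies = copies, sd_copies = 0, sem_copies = 0,
                   flags = character(0)), class = "quant_result")
  res <- list(mk("A1", "WT", 1e4), mk("A2", "WT", 2e4),
              mk("B1", "KO", 3e4), mk("B2", "KO", 3e4))
  g <- aggregate_replicates(res)
  wt <- g[g$sample_group == "WT", ]
  expect_equal(wt$mean_copies, 1.5e4)
  expect_equal(wt$sem_copies, sd(c(1e4, 2e4)) / sqrt(2))
  ko <- g[g$sample_group == "KO", ]
  expect_equal(ko$sd_copies, 0)
  ## identical quadruplicates: mean x, sd 0
  g4 <- aggregate_replicates(list(mk("C1", "G", 5), mk("C2", "G", 5),
                                  mk("C3", "G", 5), mk("C4", "G", 5)))
  expect_equal(g4$mean_copies, 5)
  expect_equal(g4$sd_copies, 0)
})

test_that("dilution-series regression reports identity and log-log slopes", {
  th <- 4.5 * 10^(5:1)
  fit <- dilution_series_fit(th, th)
  expect_equal(fit$raw$slope, 1, tolerance = 1e-12)
  expect_equal(fit$raw$r2, 1, tolerance = 1e-12)
  expect_equal(fit$log10$slope, 1, tolerance = 1e-12)
  half <- dilution_series_fit(th, 0.5 * th)
  expect_equal(half$raw$slope, 0.5, tolerance = 1e-12)
  expect_equal(half$raw$r2, 1, tolerance = 1e-12)
  expect_error(dilution_series_fit(c(1, 10), c(1, 10)),
               class = "qpcrcal_insufficient_levels")
})

test_that("pooled two-sample t-test matches the closed form", {
  eq <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  ## hand computation: s_p^2 = (5+5)/6, se = sqrt(s_p^2/2), t = -10/se
  tt <- compare_groups(c(10, 11, 12, 13), c(20, 21, 22, 23))
  expect_equal(tt$t, -10.95445, tolerance = 1e-6)
  expect_equal(tt$df, 6)
  ## degenerate zero-variance convention
  z <- compare_groups(c(2, 2), c(2, 2))
  expect_equal(z$p, 1)
  expect_error(compare_groups(1, c(1, 2)), class = "qpcrcal_insufficient_n")
})

test_that("slope-equality test follows the pooled ANCOVA form", {
  x <- 1:6
  same <- lm(I(2 * x + 1) ~ x)
  expect_equal(compare_slopes(same, same)$t, 0)
  expect_equal(compare_slopes(same, same)$p, 1)
  ## parallel lines with different intercepts: slopes do not differ
  set.seed(42)
  y1 <- 2 * x + 1 + rnorm(6, 0, 0.01)
  y2 <- 2 * x + 9 + rnorm(6, 0, 0.01)
  par_t <- compare_slopes(lm(y1 ~ x), lm(y2 ~ x))
  expect_gt(par_t$p, 0.05)
  expect_equal(par_t$df, 8)
  ## clearly different slopes with tiny residuals
  y3 <- 1.0 * x + rnorm(6, 0, 1e-4)
  y4 <- 2.0 * x + rnorm(6, 0, 1e-4)
  expect_lt(compare_slopes(lm(y3 ~ x), lm(y4 ~ x))$p, 1e-6)
  ## degenerate predictor
  xc <- rep(3, 4)
  fit_c <- lm(y ~ x2, data = data.frame(y = c(1, 2, 3, 4), x2 = xc))
  expect_error(compare_slopes(fit_c, same), class = "qpcrcal_degenerate_x")
})
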