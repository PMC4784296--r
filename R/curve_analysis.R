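#' Centered local-polynomial smoothing
#'
#' Fits a polynomial of the given degree over a sliding window of
#' `2 * half_width + 1` points and evaluates it at the window centre
#' (Savitzky-Golay family).  At the series ends the window shrinks
#' asymmetrically; the polynomial degree is reduced where fewer points than
#' `degree + 1` remain, so the filter reproduces polynomials of degree
#' `<= degree` exactly, including at the ends.
#'
#' @param y numeric series.
#' @param half_width window half width (window = `2 * half_width + 1`).
#' @param degree polynomial degree.
#' @return smoothed numeric series of the same length.
#' @export
smooth_curve <- function(y, half_width = 2L, degree = 2L) {
  n <- length(y)
  if (n < 2L * half_width + 1L)
    qc_stop("series shorter than the smoothing window", "short_curve")
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half_width)
    hi <- min(n, i + half_width)
    deg <- min(degree, hi - lo)
    x <- (lo:hi) - i
    X <- outer(x, 0:deg, `^`)
    cf <- qr.coef(qr(X), y[lo:hi])
    out[i] <- cf[1]              # polynomial value at the window centre
  }
  out
}

#' Central second difference
#'
#' `d2(n) = f(n+1) - 2 f(n) + f(n-1)` for interior cycles; the two endpoints
#' are undefined and returned as `NA`.
#'
#' @param f numeric series (length >= 3).
#' @return numeric series of the same length, `NA` at both ends.
#' @export
second_derivative <- function(f) {
  n <- length(f)
  if (n < 3L) qc_stop("need at least 3 points for a second difference", "short_curve")
  c(NA_real_, f[3:n] - 2 * f[2:(n - 1)] + f[1:(n - 2)], NA_real_)
}

## locate the interior integer cycle maximising d2 (earliest on ties) and the
## parabola-refined fractional maximum; shared by find_sdm / find_takeoff
.d2_peak <- function(f_smooth) {
  n <- length(f_smooth)
  d2 <- second_derivative(f_smooth)
  interior <- 2:(n - 1)
  m <- interior[which.max(d2[interior])]
  vertex <- m
  if (m >= 3L && m <= n - 2L) {
    denom <- d2[m - 1] - 2 * d2[m] + d2[m + 1]
    if (is.finite(denom) && denom < 0) {
      vertex <- m + 0.5 * (d2[m - 1] - d2[m + 1]) / denom
      vertex <- min(max(vertex, m - 1 + 1e-9), m + 1 - 1e-9)
    }
  }
  list(d2 = d2, m = m, vertex = vertex)
}

#' Baseline-correct a raw amplification series
#'
#' The baseline is the mean raw fluorescence over cycles `3..b` with
#' `b = max(5, floor(provisional take-off) - 3)`; the provisional take-off is
#' located on a lightly smoothed copy of the raw data.  If no amplification
#' is detectable the baseline region falls back to cycles
#' `3..min(15, n - 2)`.  An explicit `probe_region` overrides the automatic
#' choice.  Corrected values are not clipped and may be slightly negative.
#'
#' @param cycles integer cycle numbers (1-based, consecutive).
#' @param f_raw raw fluorescence, one reading per cycle.
#' @param probe_region optional integer vector of cycles to use as baseline.
#' @param half_width,degree smoothing parameters (see [smooth_curve()]).
#' @param provisional_fraction threshold fraction of the second-derivative
#'   maximum used for the provisional take-off.  This is deliberately much
#'   smaller than the reporting take-off fraction: the baseline region must
#'   end where acceleration first becomes detectable, well before the
#'   exponential signal is an appreciable fraction of the baseline.
#' @return An object of class `corrected_curve` with elements `cycles`,
#'   `f_raw`, `f_corr`, `f_smooth`, `baseline_value`, `baseline_cycles`.
#' @export
baseline_correct <- function(cycles, f_raw, probe_region = NULL,
                             half_width = 2L, degree = 2L,
                             provisional_fraction = 0.005) {
  n <- length(f_raw)
  if (length(cycles) != n)
    qc_stop("cycles and f_raw must have equal length", "ragged_plate")
  if (n < 10L) qc_stop("need at least 10 cycles", "short_curve")
  if (!is.null(probe_region)) {
    idx <- which(cycles %in% probe_region)
    if (length(idx) < 3L)
      qc_stop("fewer than 3 baseline cycles available", "short_curve")
  } else {
    s <- smooth_curve(f_raw, half_width, degree)
    b <- tryCatch({
      pk <- .d2_peak(s)
      to <- tryCatch(.takeoff_scan(pk$d2, pk$m, provisional_fraction),
                     ## already accelerating at the first cycles: no flat
                     ## baseline exists, keep the minimal region
                     qpcrcal_degenerate_curve = function(e) 8)
      max(5L, as.integer(floor(to)) - 3L)
    }, error = function(e) max(5L, min(15L, n - 2L)))
    b <- min(b, n)
    idx <- which(cycles >= 3L & cycles <= b)
    if (length(idx) < 3L)
      qc_stop("fewer than 3 baseline cycles available", "short_curve")
  }
  baseline_value <- mean(f_raw[idx])
  f_corr <- f_raw - baseline_value
  structure(list(cycles = cycles,
                 f_raw = f_raw,
                 f_corr = f_corr,
                 f_smooth = smooth_curve(f_corr, half_width, degree),
                 baseline_value = baseline_value,
                 baseline_cycles = range(cycles[idx])),
            class = "corrected_curve")
}

#' @export
print.corrected_curve <- function(x, ...) {
  cat(sprintf("<corrected_curve: %d cycles, baseline %.4g over cycles %d..%d>\n",
              length(x$cycles), x$baseline_value,
              x$baseline_cycles[1], x$baseline_cycles[2]))
  invisible(x)
}

## fourth-order-accurate central second-difference stencil (spacing 1);
## defined for indices 3..n-2, NA elsewhere
.second_diff_o4 <- function(f) {
  n <- length(f)
  out <- rep(NA_real_, n)
  if (n >= 5L)
    out[3:(n - 2)] <- (-f[5:n] + 16 * f[4:(n - 1)] - 30 * f[3:(n - 2)] +
                         16 * f[2:(n - 3)] - f[1:(n - 4)]) / 12
  out
}

#' Locate the second-derivative maximum (SDM)
#'
#' The interior integer cycle maximising the central second difference of
#' the smoothed curve anchors the search; the fractional position is then
#' refined on the unsmoothed series using a fourth-order central-difference
#' stencil interpolated densely (cubic spline through the stencil values,
#' maximised on a fine grid within 1.5 cycles of the anchor).  A 3-point
#' parabola is the fallback near the series ends.  A curve counts as
#' amplifying only when its smoothed rise exceeds ten baseline-region
#' residual standard deviations.
#'
#' @param curve a [baseline_correct()] result.
#' @return fractional cycle of the SDM.
#' @export
find_sdm <- function(curve) {
  bl <- curve$baseline_cycles
  bl_idx <- which(curve$cycles >= bl[1] & curve$cycles <= bl[2])
  sd_base <- stats::sd(curve$f_corr[bl_idx])
  rise <- max(curve$f_smooth)
  tiny <- 1e-6 * max(abs(curve$f_raw), 1)
  if (!is.finite(rise) || rise < 10 * sd_base || rise <= tiny)
    qc_stop("no amplification detected", "no_amplification")
  pk <- .d2_peak(curve$f_smooth)
  if (!is.finite(pk$d2[pk$m]) || pk$d2[pk$m] <= 0)
    qc_stop("no amplification detected", "no_amplification")
  cycle0 <- curve$cycles[1] - 1L
  m <- pk$m
  d2r <- .second_diff_o4(curve$f_corr)
  lo <- m - 5L; hi <- m + 5L
  ok <- which(!is.na(d2r))
  ok <- ok[ok >= lo & ok <= hi]
  if (length(ok) >= 4L && min(ok) <= m - 1L && max(ok) >= m + 1L) {
    sf <- stats::splinefun(ok, d2r[ok], method = "natural")
    xs <- seq(max(min(ok), m - 1.5), min(max(ok), m + 1.5), by = 0.001)
    return(xs[which.max(sf(xs))] + cycle0)
  }
  pk$vertex + cycle0            # fallback near the series ends
}

## scan d2 upward toward its maximum m and return the interpolated crossing
## of fraction * d2[m] that stays above threshold through m
.takeoff_scan <- function(d2, m, fraction) {
  th <- fraction * d2[m]
  cand <- 2:(m - 1L)
  if (m <= 2L || !length(cand) || all(d2[cand] >= th, na.rm = TRUE))
    qc_stop("second-derivative threshold never crossed before the SDM",
            "degenerate_curve")
  j <- max(cand[d2[cand] < th])
  j + (th - d2[j]) / (d2[j + 1] - d2[j])
}

#' Locate the take-off point (Cq)
#'
#' Scanning the second difference from low cycles toward the SDM, the
#' take-off is the linearly interpolated cycle where it first reaches
#' `fraction` of its maximum and stays above that threshold through the SDM.
#'
#' @param curve a [baseline_correct()] result.
#' @param fraction threshold as a fraction of the second-derivative maximum.
#' @param sdm optional precomputed [find_sdm()] value.
#' @return fractional cycle of the take-off point, always `< sdm`.
#' @export
find_takeoff <- function(curve, fraction = 0.2, sdm = NULL) {
  sdm <- sdm %||% find_sdm(curve)
  pk <- .d2_peak(curve$f_smooth)
  cycle0 <- curve$cycles[1] - 1L
  to <- .takeoff_scan(pk$d2, pk$m, fraction) + cycle0
  min(to, sdm - 1e-9)
}

#' Select the exponential window
#'
#' Integer-cycle window `ceil(takeoff) .. floor(sdm)`.  When that leaves
#' fewer than 3 cycles, the end is widened to `start + 2` only if the
#' smoothed curve is still strictly increasing there.
#'
#' @param takeoff,sdm fractional cycles from [find_takeoff()] / [find_sdm()].
#' @param curve optional `corrected_curve`, required for the widening check.
#' @return An object of class `exponential_window` with fields `takeoff`,
#'   `sdm`, `start`, `end`, `n_points`.
#' @export
select_window <- function(takeoff, sdm, curve = NULL) {
  if (!(takeoff < sdm)) qc_stop("takeoff must precede the SDM", "degenerate_curve")
  start <- as.integer(ceiling(takeoff))
  end <- as.integer(floor(sdm))
  n_points <- end - start + 1L
  if (n_points < 3L) {
    cand <- start + 2L
    widen <- FALSE
    if (!is.null(curve) && cand <= max(curve$cycles)) {
      idx <- match(start:cand, curve$cycles)
      widen <- !anyNA(idx) && all(diff(curve$f_smooth[idx]) > 0)
    }
    if (!widen)
      qc_stop("exponential window shorter than 3 cycles", "short_window")
    end <- cand
    n_points <- 3L
  }
  structure(list(takeoff = takeoff, sdm = sdm, start = start, end = end,
                 n_points = n_points),
            class = "exponential_window")
}

#' @export
print.exponential_window <- function(x, ...) {
  cat(sprintf("<exponential_window: takeoff %.2f, sdm %.2f, cycles %d..%d (%d)>\n",
              x$takeoff, x$sdm, x$start, x$end, x$n_points))
  invisible(x)
}

#' Estimate per-reaction amplification efficiency
#'
#' Ordinary least squares of `log10(f_corr)` on cycle number over the
#' exponential window; `E = 10^slope`.  Cycles with non-positive corrected
#' fluorescence are dropped; at least 3 must remain.  The estimate is
#' flagged, never clamped: `low_r2` when r2 < 0.99, `e_out_of_range` when
#' E is outside `[1.5, 2.1]`, `short_window` when the window has exactly
#' 3 cycles.
#'
#' @param curve a `corrected_curve`.
#' @param window an `exponential_window`.
#' @param r2_flag r2 below which `low_r2` is flagged.
#' @param e_range acceptable efficiency range for flagging.
#' @return An object of class `efficiency_estimate` with fields `E`, `slope`,
#'   `intercept`, `r2`, `window`, `flags`, `n_used`.
#' @export
estimate_efficiency <- function(curve, window, r2_flag = 0.99,
                                e_range = c(1.5, 2.1)) {
  cyc <- window$start:window$end
  idx <- match(cyc, curve$cycles)
  if (anyNA(idx)) qc_stop("window outside the recorded cycles", "short_window")
  y <- curve$f_corr[idx]
  keep <- is.finite(y) & y > 0
  if (sum(keep) < 3L)
    qc_stop("fewer than 3 positive window cycles", "cannot_estimate")
  fit <- ols_line(cyc[keep], log10(y[keep]))
  E <- 10^fit$slope
  flags <- character(0)
  if (fit$r2 < r2_flag) flags <- c(flags, "low_r2")
  if (E < e_range[1] || E > e_range[2]) flags <- c(flags, "e_out_of_range")
  if (window$n_points == 3L) flags <- c(flags, "short_window")
  structure(list(E = E, slope = fit$slope, intercept = fit$intercept,
                 r2 = fit$r2, window = window, flags = flags,
                 n_used = sum(keep)),
            class = "efficiency_estimate")
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf("<efficiency_estimate: E = %.4f, r2 = %.5f, %d cycles%s>\n",
              x$E, x$r2, x$n_used,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Refine the baseline by back-extrapolation
#'
#' The pre-take-off mean over-estimates the true baseline because the
#' exponential signal is already non-zero there.  This refinement fits the
#' exponential over the window, extrapolates it back into the baseline
#' region, subtracts its mean contribution from the baseline estimate and
#' iterates to a fixed point.  On noiseless exponential-plus-constant data
#' the fixed point is the exact baseline; under noise the correction is
#' small and stable (it never free-fits the baseline, which would inflate
#' efficiency variance).
#'
#' @param curve a `corrected_curve`.
#' @param window the well's `exponential_window`.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the baseline, in fluorescence units;
#'   defaults to `1e-10 * max(|f_raw|)`.
#' @return the `corrected_curve` with an updated `baseline_value`,
#'   `f_corr` and `f_smooth`; attribute `iterations` records the count.
#' @export
refine_baseline <- function(curve, window, max_iter = 12L, tol = NULL) {
  bl <- curve$baseline_cycles
  bl_cyc <- bl[1]:bl[2]
  win_cyc <- window$start:window$end
  win_idx <- match(win_cyc, curve$cycles)
  raw_mean <- mean(curve$f_raw[match(bl_cyc, curve$cycles)])
  scale <- max(abs(curve$f_raw), 1)
  tol <- tol %||% (1e-10 * scale)
  b <- curve$baseline_value
  iters <- 0L
  for (k in seq_len(max_iter)) {
    y <- curve$f_raw[win_idx] - b
    if (any(y <= 0)) break
    fit <- ols_line(win_cyc, log10(y))
    if (fit$slope <= 0) break              # not an amplifying window
    pred <- 10^(fit$intercept + fit$slope * bl_cyc)
    delta <- min(mean(pred), 0.25 * min(y))  # guard against runaway correction
    b_new <- raw_mean - delta
    iters <- k
    if (abs(b_new - b) < tol) { b <- b_new; break }
    b <- b_new
  }
  curve$baseline_value <- b
  curve$f_corr <- curve$f_raw - b
  curve$f_smooth <- smooth_curve(curve$f_corr)
  attr(curve, "iterations") <- iters
  curve
}

#' Quantification error caused by an efficiency mismatch
#'
#' Percent difference in back-calculated input between assuming perfect
#' doubling and amplifying at efficiency `E` for `n` cycles:
#' `((2^n / E^n) - 1) * 100`.
#'
#' @param E amplification efficiency (> 0).
#' @param n cycle number (>= 0).
#' @param truncate if `TRUE`, truncate toward zero for integer reporting.
#' @return percent difference.
#' @export
#' @examples
#' efficiency_error_pct(1.97, 30, truncate = TRUE)  # 57
#' efficiency_error_pct(1.90, 30, truncate = TRUE)  # 365
efficiency_error_pct <- function(E, n, truncate = FALSE) {
  if (any(E <= 0)) qc_stop("efficiency must be positive", "bad_efficiency")
  if (any(n < 0)) qc_stop("cycle number must be non-negative", "bad_cycles")
  out <- ((2^n) / (E^n) - 1) * 100
  if (truncate) trunc(out) else out
}
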