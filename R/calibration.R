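#' Convert nanograms of double-stranded DNA to picomoles
#'
#' Uses a flat average molar mass per base pair (650 g/mol/bp by default):
#' `pmol = ng * 1000 / (length_bp * bp_mass)`.
#'
#' @param ng amount in ng (>= 0).
#' @param length_bp fragment length in base pairs; the default 90 bp matches
#'   the double-stranded calibrator used throughout.
#' @param gc_frac reserved for a GC-corrected molar mass; unused by default.
#' @param bp_mass average molar mass per base pair in g/mol.
#' @return amount in pmol.
#' @export
#' @examples
#' ng_to_pmol(58.5, 90)  # 1 pmol
ng_to_pmol <- function(ng, length_bp = 90L, gc_frac = NULL, bp_mass = 650) {
  if (any(ng < 0)) qc_stop("ng must be non-negative", "bad_amount")
  if (length_bp <= 0) qc_stop("length_bp must be positive", "bad_amount")
  ng * 1000 / (length_bp * bp_mass)
}

#' Summarize one calibrator well
#'
#' The calibrator is not amplified, so its fluorescence should be constant
#' across cycles.  The first `skip_cycles` cycles are discarded (thermal
#' equilibration) and the mean and SD over the rest are reported.  A linear
#' drift larger than 5 % of the mean over the run raises a `drift` flag.
#'
#' @param f fluorescence series of the well.
#' @param meta the well's plate-map row (role must be `calibrator`).
#' @param skip_cycles leading cycles to discard.
#' @param length_bp,bp_mass calibrator fragment parameters for
#'   [ng_to_pmol()].
#' @return one-row `data.frame`: `well_id`, `loaded_ng`, `loaded_pmol`,
#'   `f_mean`, `f_sd`, `retained_first`, `retained_last`, `drift`.
#' @export
summarize_calibrator <- function(f, meta, skip_cycles = 3L,
                                 length_bp = 90L, bp_mass = 650) {
  if (!identical(meta$role, "calibrator"))
    qc_stop("summarize_calibrator expects a calibrator well", "bad_role")
  n <- length(f)
  idx <- (skip_cycles + 1L):n
  f_mean <- mean(f[idx])
  f_sd <- stats::sd(f[idx])
  fit <- ols_line(idx, f[idx])
  drift <- abs(fit$slope) * n > 0.05 * abs(f_mean) && abs(f_mean) > 0
  data.frame(well_id = meta$well,
             loaded_ng = meta$calibrator_ng,
             loaded_pmol = ng_to_pmol(meta$calibrator_ng, length_bp,
                                      bp_mass = bp_mass),
             f_mean = f_mean, f_sd = f_sd,
             retained_first = idx[1], retained_last = n,
             drift = drift,
             stringsAsFactors = FALSE)
}

#' Fit a calibration curve
#'
#' Background is the mean fluorescence of the 0 ng wells.  Replicate wells
#' at each level are averaged, the background is subtracted, and ordinary
#' least squares of background-subtracted fluorescence on pmol is fitted
#' over the non-zero levels with a free intercept.  At least one 0 ng well
#' and 5 distinct non-zero levels are required.
#'
#' @param summaries `data.frame` of [summarize_calibrator()] rows.
#' @param intercept_warn_frac warn when `|intercept|` exceeds this fraction
#'   of the fitted value at mid-range.
#' @return An object of class `calibration_curve` with fields `a` (slope,
#'   a.u. per pmol), `b` (intercept, a.u.), `r2`, `background`, `points`
#'   (`data.frame` of pmol and background-subtracted mean fluorescence) and
#'   `range_pmol`.
#' @export
fit_calibration <- function(summaries, intercept_warn_frac = 0.05) {
  zero <- summaries[summaries$loaded_ng == 0, , drop = FALSE]
  if (nrow(zero) == 0L)
    qc_stop("missing-background: no 0 ng calibrator well on the plate",
            "missing_background")
  background <- mean(zero$f_mean)
  nz <- summaries[summaries$loaded_ng > 0, , drop = FALSE]
  levels_pmol <- sort(unique(nz$loaded_pmol))
  if (length(levels_pmol) < 5L)
    qc_stop(sprintf("insufficient-levels: %d non-zero calibrator level(s), need >= 5",
                    length(levels_pmol)), "insufficient_levels")
  f_sub <- vapply(levels_pmol, function(p)
    mean(nz$f_mean[nz$loaded_pmol == p]) - background, numeric(1))
  fit <- ols_line(levels_pmol, f_sub)
  if (fit$slope <= 0)
    qc_stop("non-positive calibration slope", "non_positive_slope")
  mid <- mean(range(levels_pmol))
  mid_fit <- fit$intercept + fit$slope * mid
  if (abs(fit$intercept) > intercept_warn_frac * abs(mid_fit))
    qc_warn(sprintf(
      "calibration intercept (%.4g a.u.) exceeds %.0f%% of the mid-range fit",
      fit$intercept, 100 * intercept_warn_frac), "large_intercept")
  structure(list(a = fit$slope, b = fit$intercept, r2 = fit$r2,
                 background = background,
                 points = data.frame(pmol = levels_pmol, f_sub = f_sub),
                 range_pmol = range(levels_pmol)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(paste0("<calibration_curve: a = %.4g a.u./pmol, b = %.4g a.u., ",
                     "r2 = %.5f, background = %.4g, range %.4g..%.4g pmol>\n"),
              x$a, x$b, x$r2, x$background, x$range_pmol[1], x$range_pmol[2]))
  invisible(x)
}

#' Map background-subtracted fluorescence to pmols
#'
#' Inverts the calibration line: `pmol = (f - b) / a`.  Values falling
#' outside the calibrated range are still returned but marked in the
#' `extrapolated` attribute.
#'
#' @param curve a `calibration_curve`.
#' @param f background-subtracted fluorescence (a.u.), vectorized.
#' @return pmol values with a logical attribute `extrapolated`.
#' @export
fluorescence_to_pmol <- function(curve, f) {
  if (curve$a <= 0) qc_stop("calibration curve is unusable (a <= 0)",
                            "non_positive_slope")
  pmol <- (f - curve$b) / curve$a
  extra <- pmol < curve$range_pmol[1] | pmol > curve$range_pmol[2]
  attr(pmol, "extrapolated") <- extra
  pmol
}

#' Check that sample windows lie inside the calibrated fluorescence span
#'
#' For each sample well the corrected fluorescence over its exponential
#' window is compared with the span of the background-subtracted calibrator
#' fluorescences (0 included); the fraction of covered window cycles is
#' reported per well together with a plate-level `pass`/`warn` status.
#'
#' @param curve a `calibration_curve`.
#' @param wells_list list of `list(well_id =, curve =, window =)` entries
#'   for the sample wells.
#' @return `data.frame` with `well_id`, `coverage`, `status`; attribute
#'   `plate_status` is `"pass"` when all coverages are 1, `"warn"` otherwise.
#' @export
validate_calibrator_range <- function(curve, wells_list) {
  span <- range(c(0, curve$points$f_sub))
  rows <- lapply(wells_list, function(w) {
    idx <- match(w$window$start:w$window$end, w$curve$cycles)
    f <- w$curve$f_corr[idx]
    data.frame(well_id = w$well_id,
               coverage = mean(f >= span[1] & f <= span[2]),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(well_id = character(0), coverage = numeric(0))
  out$status <- ifelse(out$coverage == 1, "pass", "warn")
  attr(out, "plate_status") <-
    if (nrow(out) == 0L || all(out$coverage == 1)) "pass" else "warn"
  out
}

#' Serialize a calibration curve to JSON
#'
#' The stored curve can be re-applied within the same run; the CLI refuses
#' cross-run reuse by default because calibrators belong on every plate.
#'
#' @param curve a `calibration_curve`.
#' @param path output path.
#' @param run_id run the curve was fitted on.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(curve, path, run_id = "") {
  jsonlite::write_json(
    list(run_id = run_id, a = curve$a, b = curve$b, r2 = curve$r2,
         background = curve$background, points = curve$points,
         range_pmol = curve$range_pmol),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration curve from JSON
#' @param path path written by [write_calibration_json()].
#' @return a `calibration_curve`; attribute `run_id` records its origin.
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- structure(list(a = x$a, b = x$b, r2 = x$r2, background = x$background,
                        points = as.data.frame(x$points),
                        range_pmol = as.numeric(x$range_pmol)),
                   class = "calibration_curve")
  attr(out, "run_id") <- x$run_id %||% ""
  out
}
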