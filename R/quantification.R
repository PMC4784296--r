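#' Convert picomoles to copies per reaction
#'
#' `copies = pmol * 6.022e23 * 1e-12`.
#'
#' @param pmol amount in pmol.
#' @return copies per reaction.
#' @export
#' @examples
#' pmol_to_copies(1)  # 6.022e11
pmol_to_copies <- function(pmol) pmol * COPIES_PER_PMOL

#' Convert copies per reaction to picomoles
#' @param copies copies per reaction.
#' @return amount in pmol.
#' @export
copies_to_pmol <- function(copies) copies / COPIES_PER_PMOL

#' Back-calculate the starting amount of one well
#'
#' For every integer cycle `n` of the exponential window the corrected
#' fluorescence is mapped to pmols through the calibration curve
#' (`pm(n)`), then projected back to cycle zero with the well's own
#' efficiency: `pmz(n) = pm(n) / E^n` (`n` counts from cycle 1, i.e.
#' amplification proceeds at efficiency E from the first cycle).  Cycles
#' with non-positive `pm` are dropped; at least 3 must remain.  The mean,
#' SD and SEM over the retained cycles are reported in pmols and in copies
#' per reaction.
#'
#' @param curve the well's `corrected_curve`.
#' @param eff the well's `efficiency_estimate`.
#' @param cal the plate's `calibration_curve`.
#' @param meta optional plate-map row (well, target, sample_group, replicate).
#' @return An object of class `quant_result`.
#' @export
quantify_well <- function(curve, eff, cal, meta = NULL) {
  if (!is.finite(eff$E) || eff$E <= 1)
    qc_stop("invalid efficiency (E <= 1)", "invalid_efficiency")
  win <- eff$window
  cyc <- win$start:win$end
  idx <- match(cyc, curve$cycles)
  pm <- fluorescence_to_pmol(cal, curve$f_corr[idx])
  extrapolated <- attr(pm, "extrapolated")
  keep <- is.finite(pm) & pm > 0
  n_dropped <- sum(!keep)
  if (sum(keep) < 3L)
    qc_stop("fewer than 3 retained window cycles", "cannot_quantify")
  cyc <- cyc[keep]
  pm <- as.numeric(pm[keep])
  pmz <- pm / eff$E^cyc
  flags <- eff$flags
  if (any(extrapolated[keep])) flags <- union(flags, "extrapolated")
  if (n_dropped > 0L) flags <- union(flags, "dropped_cycles")
  structure(list(
    well_id = meta$well %||% "",
    target = meta$target %||% "",
    sample_group = meta$sample_group %||% "",
    replicate = meta$replicate %||% NA_integer_,
    E = eff$E, window = win,
    per_cycle = data.frame(cycle = cyc, pm = pm, pmz = pmz),
    n_retained = length(pmz), n_dropped = n_dropped,
    mean_pmz = mean(pmz), sd_pmz = stats::sd(pmz), sem_pmz = sem(pmz),
    mean_copies = pmol_to_copies(mean(pmz)),
    sd_copies = pmol_to_copies(stats::sd(pmz)),
    sem_copies = pmol_to_copies(sem(pmz)),
    flags = flags),
    class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result %s: %.4g copies/PCR (SEM %.3g), E = %.4f, cycles %d..%d%s>\n",
              x$well_id, x$mean_copies, x$sem_copies, x$E,
              x$window$start, x$window$end,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Aggregate replicate wells into group statistics
#'
#' Mean, SD and SEM of the per-well `mean_copies` over replicate wells
#' within each (target, sample_group).  Wells without a finite estimate
#' (e.g. non-amplifying) are excluded; empty groups are omitted.
#'
#' @param results list of [quantify_well()] results or a [quant_table()]
#'   `data.frame`.
#' @return `data.frame` with `target`, `sample_group`, `n`, `mean_copies`,
#'   `sd_copies`, `sem_copies`.
#' @export
aggregate_replicates <- function(results) {
  df <- if (is.data.frame(results)) results else quant_table(results)
  df <- df[is.finite(df$mean_copies), , drop = FALSE]
  if (nrow(df) == 0L)
    return(data.frame(target = character(0), sample_group = character(0),
                      n = integer(0), mean_copies = numeric(0),
                      sd_copies = numeric(0), sem_copies = numeric(0)))
  key <- interaction(df$target, df$group, drop = TRUE, sep = "\r")
  rows <- lapply(split(df, key), function(g) {
    x <- g$mean_copies
    data.frame(target = g$target[1], sample_group = g$group[1],
               n = length(x), mean_copies = mean(x),
               sd_copies = if (length(x) > 1) stats::sd(x) else 0,
               sem_copies = if (length(x) > 1) sem(x) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regress determined against theoretical copy numbers
#'
#' Fits the agreement line between the known input of a dilution series and
#' the determined copies, both on the identity scale and on log10-log10
#' scale.  Perfect quantification gives slope 1, r2 1 on both.
#'
#' @param theoretical known input copies per reaction.
#' @param determined measured copies per reaction.
#' @return list with components `raw` and `log10`, each containing `slope`,
#'   `intercept`, `r2`.
#' @export
dilution_series_fit <- function(theoretical, determined) {
  if (length(theoretical) != length(determined))
    qc_stop("theoretical and determined must have equal length", "bad_format")
  if (length(unique(theoretical)) < 3L)
    qc_stop("need at least 3 dilution levels", "insufficient_levels")
  raw <- ols_line(theoretical, determined)
  keep <- theoretical > 0 & determined > 0
  lg <- ols_line(log10(theoretical[keep]), log10(determined[keep]))
  list(raw = raw[c("slope", "intercept", "r2")],
       log10 = lg[c("slope", "intercept", "r2")])
}

#' Two-sample t-test between groups
#'
#' Unpaired, two-sided Student's t-test with pooled variance (Welch by
#' flag).  When both groups have zero variance the test is degenerate:
#' equal means give `t = 0, p = 1` by convention, unequal means
#' `t = +-Inf, p = 0`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use the Welch (unequal-variance) form.
#' @return list with `t`, `df`, `p`.
#' @export
compare_groups <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    qc_stop("each group needs at least 2 observations", "insufficient_n")
  df_pooled <- length(a) + length(b) - 2L
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    d <- mean(a) - mean(b)
    if (d == 0) return(list(t = 0, df = df_pooled, p = 1))
    return(list(t = sign(d) * Inf, df = df_pooled, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Test equality of two regression slopes
#'
#' Two-sided t-test on the slope difference of two simple linear
#' regressions, using the pooled residual variance (common-variance ANCOVA
#' form) with `df = nA + nB - 4`.
#'
#' @param fit_a,fit_b `lm` objects of the form `lm(y ~ x)`.
#' @return list with `t`, `df`, `p`, `slope_a`, `slope_b`.
#' @export
compare_slopes <- function(fit_a, fit_b) {
  part <- function(fit) {
    x <- fit$model[[2]]
    if (length(x) < 3L) qc_stop("each fit needs at least 3 points", "insufficient_n")
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) qc_stop("predictor has zero variance", "degenerate_x")
    list(slope = unname(stats::coef(fit)[2]), rss = sum(stats::resid(fit)^2),
         sxx = sxx, n = length(x))
  }
  pa <- part(fit_a); pb <- part(fit_b)
  df <- pa$n + pb$n - 4L
  s2 <- (pa$rss + pb$rss) / df
  se <- sqrt(s2 * (1 / pa$sxx + 1 / pb$sxx))
  d <- pa$slope - pb$slope
  t <- if (se > 0) d / se else if (d == 0) 0 else sign(d) * Inf
  p <- if (is.finite(t)) 2 * stats::pt(-abs(t), df) else 0
  list(t = t, df = df, p = p, slope_a = pa$slope, slope_b = pb$slope)
}
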