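#' Analyze one well's raw fluorescence series
#'
#' Baseline correction, landmark detection (take-off and SDM), exponential
#' window selection, optional baseline refinement, and efficiency
#' estimation.
#'
#' @param cycles integer cycle numbers.
#' @param f raw fluorescence series.
#' @param takeoff_fraction threshold fraction for [find_takeoff()].
#' @param half_width,degree smoothing parameters.
#' @param refine run [refine_baseline()] before the efficiency fit.
#' @param probe_region optional explicit baseline cycle range.
#' @return list with `curve`, `window`, `eff`.
#' @export
analyze_well <- function(cycles, f, takeoff_fraction = 0.2,
                         half_width = 2L, degree = 2L, refine = TRUE,
                         probe_region = NULL) {
  curve <- baseline_correct(cycles, f, probe_region = probe_region,
                            half_width = half_width, degree = degree)
  sdm <- find_sdm(curve)
  takeoff <- find_takeoff(curve, fraction = takeoff_fraction, sdm = sdm)
  window <- select_window(takeoff, sdm, curve)
  if (refine) curve <- refine_baseline(curve, window)
  eff <- estimate_efficiency(curve, window)
  list(curve = curve, window = window, eff = eff)
}

#' Fit the plate's calibration curve
#'
#' Summarizes every calibrator well of an annotated plate run and fits the
#' calibration line (see [fit_calibration()]).
#'
#' @param run an annotated `plate_run`.
#' @param skip_cycles leading calibrator cycles to discard.
#' @param cal_length_bp calibrator fragment length in bp.
#' @param bp_mass average molar mass per base pair (g/mol).
#' @return a `calibration_curve`.
#' @export
calibrate_plate <- function(run, skip_cycles = 3L, cal_length_bp = 90L,
                            bp_mass = 650) {
  if (is.null(run$meta))
    qc_stop("plate run has no metadata; call attach_metadata() first",
            "missing_metadata")
  cal_idx <- which(run$meta$role == "calibrator")
  if (!length(cal_idx))
    qc_stop("missing-background: no calibrator wells on the plate",
            "missing_background")
  summaries <- do.call(rbind, lapply(cal_idx, function(i)
    summarize_calibrator(run$fluor[, i], run$meta[i, ],
                         skip_cycles = skip_cycles,
                         length_bp = cal_length_bp, bp_mass = bp_mass)))
  fit_calibration(summaries)
}

## placeholder report row for wells that could not be quantified
.failed_result <- function(meta, flag) {
  structure(list(well_id = meta$well, target = meta$target,
                 sample_group = meta$sample_group, replicate = meta$replicate,
                 E = NA_real_, window = NULL,
                 per_cycle = data.frame(cycle = integer(0), pm = numeric(0),
                                        pmz = numeric(0)),
                 n_retained = 0L, n_dropped = 0L,
                 mean_pmz = NA_real_, sd_pmz = NA_real_, sem_pmz = NA_real_,
                 mean_copies = NA_real_, sd_copies = NA_real_,
                 sem_copies = NA_real_, flags = flag),
            class = "quant_result")
}

#' Quantify every sample well of a plate
#'
#' Runs the full workflow: calibration (unless a curve is supplied), then
#' per-well curve analysis and back-calculation.  Non-amplifying or
#' otherwise unquantifiable wells (including NTCs) are reported with a flag
#' naming the failure instead of aborting the plate.
#'
#' @param run an annotated `plate_run`.
#' @param calibration optional precomputed `calibration_curve`.
#' @param takeoff_fraction threshold fraction for [find_takeoff()].
#' @param refine_baseline run the baseline refinement (see
#'   [refine_baseline()]).
#' @param cal_length_bp,bp_mass calibrator conversion parameters.
#' @return list with `calibration`, `results` (list of `quant_result`),
#'   `table` (the report `data.frame`).
#' @export
quantify_plate <- function(run, calibration = NULL, takeoff_fraction = 0.2,
                           refine_baseline = TRUE, cal_length_bp = 90L,
                           bp_mass = 650) {
  if (is.null(run$meta))
    qc_stop("plate run has no metadata; call attach_metadata() first",
            "missing_metadata")
  cal <- calibration %||% calibrate_plate(run, cal_length_bp = cal_length_bp,
                                          bp_mass = bp_mass)
  idx <- which(run$meta$role %in% c("sample", "ntc"))
  results <- lapply(idx, function(i) {
    meta <- run$meta[i, ]
    tryCatch({
      an <- analyze_well(run$cycles, run$fluor[, i],
                         takeoff_fraction = takeoff_fraction,
                         refine = refine_baseline)
      quantify_well(an$curve, an$eff, cal, meta = meta)
    }, qpcrcal_error = function(e) {
      flag <- sub("^qpcrcal_", "", class(e)[1])
      .failed_result(meta, flag)
    })
  })
  names(results) <- run$meta$well[idx]
  list(calibration = cal, results = results, table = quant_table(results))
}

#' Flatten quantification results into a report table
#'
#' @param results list of `quant_result` objects.
#' @return `data.frame`, one row per well, with the report columns
#'   (`well`, `target`, `group`, `replicate`, `E`, `takeoff`, `sdm`,
#'   `window_start`, `window_end`, pmol and copies statistics, `flags`).
#' @export
quant_table <- function(results) {
  if (!length(results))
    return(data.frame(well = character(0), target = character(0),
                      group = character(0), replicate = integer(0),
                      E = numeric(0), takeoff = numeric(0), sdm = numeric(0),
                      window_start = integer(0), window_end = integer(0),
                      mean_pmz = numeric(0), sd_pmz = numeric(0),
                      sem_pmz = numeric(0), mean_copies = numeric(0),
                      sd_copies = numeric(0), sem_copies = numeric(0),
                      flags = character(0), stringsAsFactors = FALSE))
  rows <- lapply(results, function(r) {
    w <- r$window
    data.frame(well = r$well_id, target = r$target, group = r$sample_group,
               replicate = r$replicate, E = r$E,
               takeoff = if (is.null(w)) NA_real_ else w$takeoff,
               sdm = if (is.null(w)) NA_real_ else w$sdm,
               window_start = if (is.null(w)) NA_integer_ else w$start,
               window_end = if (is.null(w)) NA_integer_ else w$end,
               mean_pmz = r$mean_pmz, sd_pmz = r$sd_pmz, sem_pmz = r$sem_pmz,
               mean_copies = r$mean_copies, sd_copies = r$sd_copies,
               sem_copies = r$sem_copies,
               flags = paste(r$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a Cq table from quantification results
#'
#' The take-off point serves as Cq and the per-reaction efficiency estimate
#' is carried along for the Pfaffl ratio.  Non-amplifying wells are
#' excluded.
#'
#' @param results list of `quant_result` objects (or the list element
#'   `results` of [quantify_plate()]).
#' @return Cq table `data.frame` (`sample_group`, `target`, `replicate`,
#'   `cq`, `efficiency`).
#' @export
cq_from_results <- function(results) {
  rows <- lapply(results, function(r) {
    if (is.null(r$window) || !is.finite(r$E)) return(NULL)
    data.frame(sample_group = r$sample_group, target = r$target,
               replicate = r$replicate, cq = r$window$takeoff,
               efficiency = r$E, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(sample_group = character(0), target = character(0),
                      replicate = integer(0), cq = numeric(0),
                      efficiency = numeric(0))
  rownames(out) <- NULL
  out
}
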