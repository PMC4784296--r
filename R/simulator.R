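#' Simulation configuration
#'
#' Defines one synthetic plate: amplification kinetics, calibrator design,
#' signal scaling and noise.  Defaults mirror a typical dye-based run: 40
#' cycles, six ten-fold dilutions of 4.5e6..4.5e1 starting copies in
#' quadruplicate, seven calibrator amounts (0, 40, 60, 80, 120, 140, 200 ng
#' of a 90 bp fragment) in duplicate, two no-template controls, efficiency
#' 1.9, and 1 % multiplicative fluorescence noise.
#'
#' Two kinetic models are available.  `ideal`: copies grow exactly as
#' `N(n) = min(N0 * E0^n, K)` -- exact closed-form truth for correctness
#' tests.  `logistic`: the per-cycle efficiency declines as product
#' accumulates, `E(n) = 1 + (E0 - 1) / (1 + N(n-1)/K)` -- a realistic,
#' smoothly saturating curve for robustness tests.
#'
#' @param n_cycles number of PCR cycles.
#' @param model `"ideal"` or `"logistic"`.
#' @param E0 initial amplification efficiency, in (1, 2].
#' @param cal_slope fluorescence per pmol of double-stranded DNA (a.u./pmol).
#' @param cal_background fluorescence of a 0 ng calibrator well (a.u.).
#' @param sample_baseline baseline fluorescence of sample wells (a.u.).
#' @param plateau_copies plateau capacity K in copies per reaction.
#' @param noise_sd_frac SD of multiplicative Gaussian noise, as a fraction
#'   of the signal.
#' @param additive_sd SD of additive Gaussian noise (a.u.).
#' @param seed master seed; every well derives its own stream from it, so
#'   adding wells never perturbs existing ones.
#' @param dilution_copies starting copies of the sample dilution levels.
#' @param dilution_replicates replicate wells per dilution level.
#' @param calibrator_ng calibrator amounts in ng (must include 0).
#' @param calibrator_replicates replicate wells per calibrator amount.
#' @param n_ntc number of no-template control wells.
#' @param cal_length_bp calibrator fragment length in bp.
#' @param samples optional `data.frame(target, sample_group, replicate, n0)`
#'   replacing the default dilution-series sample layout.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cycles = 40L,
                       model = c("ideal", "logistic"),
                       E0 = 1.9,
                       cal_slope = 2000,
                       cal_background = 300,
                       sample_baseline = 50,
                       plateau_copies = 1e12,
                       noise_sd_frac = 0.01,
                       additive_sd = 0,
                       seed = 1L,
                       dilution_copies = 4.5 * 10^(6:1),
                       dilution_replicates = 4L,
                       calibrator_ng = c(0, 40, 60, 80, 120, 140, 200),
                       calibrator_replicates = 2L,
                       n_ntc = 2L,
                       cal_length_bp = 90L,
                       samples = NULL) {
  model <- match.arg(model)
  if (!(E0 > 1 && E0 <= 2)) qc_stop("E0 must be in (1, 2]", "bad_config")
  if (any(c(cal_slope, plateau_copies) <= 0) ||
      any(c(cal_background, sample_baseline, noise_sd_frac, additive_sd,
            dilution_copies, calibrator_ng) < 0))
    qc_stop("amounts, scales and noise levels must be non-negative", "bad_config")
  if ((noise_sd_frac > 0 || additive_sd > 0) && is.null(seed))
    qc_stop("a seed is mandatory for any stochastic run", "bad_config")
  structure(list(n_cycles = as.integer(n_cycles), model = model, E0 = E0,
                 cal_slope = cal_slope, cal_background = cal_background,
                 sample_baseline = sample_baseline,
                 plateau_copies = plateau_copies,
                 noise_sd_frac = noise_sd_frac, additive_sd = additive_sd,
                 seed = as.integer(seed),
                 dilution_copies = dilution_copies,
                 dilution_replicates = as.integer(dilution_replicates),
                 calibrator_ng = calibrator_ng,
                 calibrator_replicates = as.integer(calibrator_replicates),
                 n_ntc = as.integer(n_ntc),
                 cal_length_bp = as.integer(cal_length_bp),
                 samples = samples),
            class = "sim_config")
}

## deterministic per-well seed below 2^31, derived from the master seed
.well_seed <- function(seed, well_index) {
  (abs(seed) %% 65521L) * 32003L + well_index * 101L
}

.add_noise <- function(f, cfg, well_index) {
  if (cfg$noise_sd_frac == 0 && cfg$additive_sd == 0) return(f)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.well_seed(cfg$seed, well_index))
  n <- length(f)
  f * (1 + stats::rnorm(n, 0, cfg$noise_sd_frac)) +
    stats::rnorm(n, 0, cfg$additive_sd)
}

#' Simulate one amplification curve
#'
#' @param cfg a [sim_config()].
#' @param n0 starting copies per reaction (0 gives a no-template well).
#' @param well_index integer index seeding this well's noise stream.
#' @return list with `f` (fluorescence series) and `truth`
#'   (`n0`, `e0`, `model`, per-cycle true copies `n_copies`).
#' @export
simulate_curve <- function(cfg, n0, well_index = 0L) {
  cyc <- seq_len(cfg$n_cycles)
  if (cfg$model == "ideal" || n0 == 0) {
    n_copies <- pmin(n0 * cfg$E0^cyc, cfg$plateau_copies)
  } else {
    n_copies <- numeric(cfg$n_cycles)
    prev <- n0
    for (n in cyc) {
      e_n <- 1 + (cfg$E0 - 1) / (1 + prev / cfg$plateau_copies)
      prev <- prev * e_n
      n_copies[n] <- prev
    }
  }
  f <- cfg$sample_baseline + cfg$cal_slope * copies_to_pmol(n_copies)
  list(f = .add_noise(f, cfg, well_index),
       truth = list(n0 = n0, e0 = cfg$E0, model = cfg$model,
                    n_copies = n_copies))
}

#' Simulate one calibrator well
#'
#' The calibrator is cycled but never amplified, so its expected
#' fluorescence is constant: `cal_background + cal_slope * pmol(ng)`.
#'
#' @param cfg a [sim_config()].
#' @param ng loaded calibrator amount in ng (>= 0).
#' @param well_index integer index seeding this well's noise stream.
#' @return list with `f` and `truth` (`ng`, `pmol`, expected fluorescence).
#' @export
simulate_calibrator_well <- function(cfg, ng, well_index = 0L) {
  if (ng < 0) qc_stop("ng must be non-negative", "bad_amount")
  pmol <- ng_to_pmol(ng, cfg$cal_length_bp)
  f0 <- cfg$cal_background + cfg$cal_slope * pmol
  f <- rep(f0, cfg$n_cycles)
  list(f = .add_noise(f, cfg, well_index),
       truth = list(ng = ng, pmol = pmol, f_expected = f0))
}

.well_id <- function(i) {
  paste0(LETTERS[(i - 1L) %/% 12L + 1L], (i - 1L) %% 12L + 1L)
}

#' Simulate a whole plate
#'
#' Builds the sample wells (the dilution series by default, or
#' `cfg$samples`), calibrator wells and no-template controls, assembles a
#' `plate_run` with its plate map attached, and optionally writes the wide
#' fluorescence CSV, the plate-map CSV and a ground-truth JSON to `dir`.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory; created if missing.
#' @param run_id run identifier (also used for the file names).
#' @return list with `run` (annotated `plate_run`), `map`, `truth`
#'   (`data.frame` per well) and, when `dir` is given, `paths`.
#' @export
simulate_plate <- function(cfg, dir = NULL, run_id = "simulated_plate") {
  samples <- cfg$samples
  if (is.null(samples)) {
    lv <- seq_along(cfg$dilution_copies)
    samples <- data.frame(
      target = "lambda",
      sample_group = sprintf("lvl%02d", rep(lv, each = cfg$dilution_replicates)),
      replicate = rep(seq_len(cfg$dilution_replicates), times = length(lv)),
      n0 = rep(cfg$dilution_copies, each = cfg$dilution_replicates),
      stringsAsFactors = FALSE)
  }
  cal <- data.frame(
    ng = rep(cfg$calibrator_ng, each = cfg$calibrator_replicates),
    replicate = rep(seq_len(cfg$calibrator_replicates),
                    times = length(cfg$calibrator_ng)))
  n_wells <- nrow(samples) + nrow(cal) + cfg$n_ntc
  ids <- vapply(seq_len(n_wells), .well_id, character(1))
  fluor <- matrix(NA_real_, nrow = cfg$n_cycles, ncol = n_wells,
                  dimnames = list(NULL, ids))
  meta <- data.frame(well = ids, role = NA_character_, target = "",
                     sample_group = "", replicate = 1L,
                     calibrator_ng = NA_real_, detection = "dye",
                     stringsAsFactors = FALSE)
  truth <- data.frame(well = ids, role = NA_character_, n0 = NA_real_,
                      e0 = NA_real_, model = cfg$model,
                      stringsAsFactors = FALSE)
  i <- 0L
  for (s in seq_len(nrow(samples))) {
    i <- i + 1L
    sim <- simulate_curve(cfg, samples$n0[s], well_index = i)
    fluor[, i] <- sim$f
    meta[i, c("role", "target", "sample_group")] <-
      c("sample", samples$target[s], samples$sample_group[s])
    meta$replicate[i] <- samples$replicate[s]
    truth[i, c("role", "n0", "e0")] <- list("sample", samples$n0[s], cfg$E0)
  }
  for (k in seq_len(nrow(cal))) {
    i <- i + 1L
    sim <- simulate_calibrator_well(cfg, cal$ng[k], well_index = i)
    fluor[, i] <- sim$f
    meta$role[i] <- "calibrator"
    meta$sample_group[i] <- "cal"
    meta$replicate[i] <- cal$replicate[k]
    meta$calibrator_ng[i] <- cal$ng[k]
    truth$role[i] <- "calibrator"
  }
  for (k in seq_len(cfg$n_ntc)) {
    i <- i + 1L
    sim <- simulate_curve(cfg, 0, well_index = i)
    fluor[, i] <- sim$f
    meta$role[i] <- "ntc"
    meta$sample_group[i] <- "ntc"
    meta$replicate[i] <- k
    truth[i, c("role", "n0")] <- list("ntc", 0)
  }
  run <- new_plate_run(seq_len(cfg$n_cycles), fluor, run_id = run_id)
  run <- attach_metadata(run, meta)
  out <- list(run = run, map = meta, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fl_path <- file.path(dir, paste0(run_id, "_fluorescence.csv"))
    map_path <- file.path(dir, paste0(run_id, "_plate_map.csv"))
    truth_path <- file.path(dir, paste0(run_id, "_truth.json"))
    wide <- data.frame(cycle = seq_len(cfg$n_cycles), fluor,
                       check.names = FALSE)
    utils::write.csv(wide, fl_path, row.names = FALSE)
    map_out <- meta
    map_out$calibrator_ng[is.na(map_out$calibrator_ng)] <- ""
    utils::write.csv(map_out, map_path, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(truth, truth_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
    out$paths <- list(fluorescence = fl_path, plate_map = map_path,
                      truth = truth_path)
  }
  out
}
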