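## shared fixture builders; everything is generated in code at test time

## logistic amplification curve sampled at integer cycles
logistic_curve <- function(n_cycles = 40, midpoint = 25, slope = 1.5,
                           amplitude = 1000, baseline = 0) {
  n <- seq_len(n_cycles)
  baseline + amplitude / (1 + exp(-(n - midpoint) / slope))
}

## analytic SDM of the logistic above (maximum of its second derivative)
logistic_sdm_truth <- function(midpoint, slope) {
  midpoint - slope * log(2 + sqrt(3))
}

## ideal exponential-with-plateau sample well over a flat baseline
ideal_curve <- function(n_cycles = 40, n0 = 1e4, e0 = 1.9, a = 2000,
                        baseline = 50, plateau_copies = 1e12) {
  n <- seq_len(n_cycles)
  baseline + a * copies_to_pmol(pmin(n0 * e0^n, plateau_copies))
}

## default noiseless config for exact round-trip checks
noiseless_cfg <- function(...) {
  sim_config(noise_sd_frac = 0, additive_sd = 0, ...)
}

## write a wide fluorescence CSV + plate map for a 3-well toy plate
write_toy_plate <- function(dir, drop_cycle = NULL) {
  n <- 40
  f <- cbind(A1 = ideal_curve(n), A2 = ideal_curve(n, n0 = 1e5),
             B2 = ideal_curve(n, n0 = 1e3))
  wide <- data.frame(cycle = seq_len(n), f, check.names = FALSE)
  fl <- file.path(dir, "fluor.csv")
  utils::write.csv(wide, fl, row.names = FALSE)
  long <- data.frame(well = rep(colnames(f), each = n),
                     cycle = rep(seq_len(n), times = 3),
                     fluorescence = as.vector(f))
  if (!is.null(drop_cycle))
    long <- long[!(long$well == "B2" & long$cycle == drop_cycle), ]
  lg <- file.path(dir, "fluor_long.csv")
  utils::write.csv(long, lg, row.names = FALSE)
  list(wide = fl, long = lg, fluor = f)
}
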