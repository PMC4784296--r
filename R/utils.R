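## internal helpers: classed conditions so callers can distinguish failure modes
## (e.g. a non-amplifying NTC well must not abort a whole plate)

qc_stop <- function(msg, class) {
  stop(structure(
    class = c(paste0("qpcrcal_", class), "qpcrcal_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

qc_warn <- function(msg, class = "warning") {
  warning(structure(
    class = c(paste0("qpcrcal_", class), "qpcrcal_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))

## closed-form simple OLS of y on x; returns slope, intercept, r2, rss, sxx
ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) qc_stop("predictor has zero variance", "degenerate_x")
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  fitted <- intercept + slope * x
  rss <- sum((y - fitted)^2)
  tss <- sum((y - my)^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  list(slope = slope, intercept = intercept, r2 = r2, rss = rss, sxx = sxx, n = n)
}
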