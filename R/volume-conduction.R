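#' Normalized cross-correlation by lag
#'
#' Pearson correlation between two equal-length series at every lag from
#' `-max_lag` to `+max_lag`, computed over the overlapping samples at each
#' lag. The peak sits at lag `L` when `y` is a copy of `x` delayed by `L`
#' samples (`y[t] = x[t - L]`).
#'
#' @param x,y Numeric vectors of equal length.
#' @param max_lag Maximum lag in samples (`< length(x)`).
#' @return Data frame with columns `lag` and `r`.
#' @export
cross_correlate <- function(x, y, max_lag = 10L) {
  n <- length(x)
  if (length(y) != n)
    stop("cross_correlate: series must have equal length", call. = FALSE)
  max_lag <- as.integer(max_lag)
  if (max_lag >= n - 2L)
    stop("cross_correlate: max_lag too large for the series length",
         call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("cross_correlate: zero-variance input", call. = FALSE)
  lags <- seq.int(-max_lag, max_lag)
  r <- vapply(lags, function(L) {
    if (L >= 0) stats::cor(x[1:(n - L)], y[(1 + L):n])
    else stats::cor(x[(1 - L):n], y[1:(n + L)])
  }, numeric(1))
  data.frame(lag = lags, r = r)
}

#' JZS Bayes factor for a Pearson correlation
#'
#' Natural-log Bayes factor BF10 for a nonzero correlation against the point
#' null, under the Jeffreys-Zellner-Siow prior:
#' \deqn{BF_{10} = \frac{\sqrt{n/2}}{\Gamma(1/2)} \int_0^\infty
#'   (1+g)^{(n-2)/2}\,[1+(1-r^2)\,g]^{-(n-1)/2}\, g^{-3/2}\,
#'   e^{-n/(2g)}\, dg}
#' evaluated by adaptive numerical integration. Values above 0 favour a
#' nonzero correlation; in the volume-conduction check, ln BF10 > 1.1 counts
#' as substantial and > 2.3 as strong evidence for a shared (volume
#' conducted) signal.
#'
#' @param r Observed Pearson correlation, `|r| < 1`.
#' @param n Number of paired samples, `n >= 3`.
#' @return `ln(BF10)` (scalar).
#' @export
jzs_ln_bf10 <- function(r, n) {
  if (!is.finite(r) || abs(r) >= 1)
    stop("jzs_ln_bf10: need |r| < 1 (BF diverges at |r| = 1)", call. = FALSE)
  if (n < 3) stop("jzs_ln_bf10: need n >= 3", call. = FALSE)
  # integrate on u = log(g) for numerical stability across scales;
  # log-integrand evaluated directly to avoid overflow at large n
  log_f <- function(u) {
    g <- exp(u)
    (n - 2) / 2 * log1p(g) - (n - 1) / 2 * log1p((1 - r^2) * g) -
      1.5 * u - n / (2 * g) + u   # + u from the Jacobian dg = g du
  }
  peak <- stats::optimize(log_f, c(-10, 30), maximum = TRUE)$objective
  val <- stats::integrate(function(u) exp(log_f(u) - peak),
                          lower = -20, upper = 40,
                          rel.tol = 1e-10, subdivisions = 400L)$value
  log(sqrt(n / 2) / gamma(0.5)) + peak + log(val)
}

#' Zero-lag Bayesian correlation check against companion EEG
#'
#' For every EEG channel: the per-trial zero-lag Pearson correlation with
#' the CI series, its average across trials, the mean of the per-trial
#' ln BF10 values, and the ln BF10 of the trial-averaged correlation. The
#' verdict per channel compares the aggregated ln BF10 with the evidence
#' thresholds (default 1.1 substantial, 2.3 strong on the ln scale).
#'
#' @param series_set A `ci_series_set` (the CI trials).
#' @param companion A `ci_eeg_companion` with matching trial count.
#' @param thresholds Named numeric `c(substantial =, strong =)` ln-BF
#'   thresholds.
#' @param exclude_channels Integer indices of channels to drop (e.g.
#'   electrodes above the implant).
#' @param aggregate Which per-channel ln BF feeds the verdict:
#'   `"mean_trial_bf"` (mean of per-trial ln BF10, default) or `"bf_of_mean_r"`.
#' @return A `ci_bayes_corr`: data frame `channels` (channel, mean_r,
#'   mean_ln_bf10, ln_bf10_mean_r, verdict) plus `summary` (mean and SD of
#'   the aggregated ln BF10 across channels), `thresholds`, `n_trials`.
#' @export
assess_volume_conduction <- function(series_set, companion,
                                     thresholds = c(substantial = 1.1,
                                                    strong = 2.3),
                                     exclude_channels = NULL,
                                     aggregate = c("mean_trial_bf",
                                                   "bf_of_mean_r")) {
  stopifnot(inherits(series_set, "ci_series_set"),
            inherits(companion, "ci_eeg_companion"))
  aggregate <- match.arg(aggregate)
  if (thresholds["substantial"] >= thresholds["strong"])
    stop("assess_volume_conduction: substantial threshold must lie below ",
         "strong", call. = FALSE)
  ci <- series_set$series
  chan <- companion$channels
  if (dim(chan)[3] != ncol(ci) || dim(chan)[1] != nrow(ci))
    stop("assess_volume_conduction: CI and EEG trial/sample counts differ",
         call. = FALSE)
  keep <- setdiff(seq_len(dim(chan)[2]), exclude_channels)
  n_samp <- nrow(ci)

  rows <- lapply(keep, function(c_i) {
    r_t <- vapply(seq_len(ncol(ci)), function(tr)
      stats::cor(ci[, tr], chan[, c_i, tr]), numeric(1))
    r_t <- pmin(pmax(r_t, -0.999999), 0.999999)
    lbf_t <- vapply(r_t, jzs_ln_bf10, numeric(1), n = n_samp)
    mean_r <- mean(r_t)
    data.frame(channel = c_i, mean_r = mean_r,
               mean_ln_bf10 = mean(lbf_t),
               ln_bf10_mean_r = jzs_ln_bf10(mean_r, n_samp))
  })
  channels <- do.call(rbind, rows)
  agg <- if (aggregate == "mean_trial_bf") channels$mean_ln_bf10 else
    channels$ln_bf10_mean_r
  channels$verdict <- ifelse(agg > thresholds["strong"], "strong",
                             ifelse(agg > thresholds["substantial"],
                                    "substantial", "none"))
  structure(list(channels = channels,
                 summary = c(mean = mean(agg), sd = stats::sd(agg)),
                 thresholds = thresholds, aggregate = aggregate,
                 n_trials = ncol(ci)),
            class = "ci_bayes_corr")
}

#' @export
print.ci_bayes_corr <- function(x, ...) {
  cat("<ci_bayes_corr> ", nrow(x$channels), " channels, ", x$n_trials,
      " trials; ln BF10 (", x$aggregate, "): mean = ",
      round(x$summary["mean"], 3), ", SD = ", round(x$summary["sd"], 3),
      "; verdicts: ", paste(names(table(x$channels$verdict)),
                            table(x$channels$verdict), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
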