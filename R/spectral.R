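#' Frequency bands of interest
#'
#' The four analysis bands on the 1 Hz grid of a 1 s window: broadband
#' 4-25 Hz, theta 5-8 Hz, alpha 9-13 Hz, beta 14-24 Hz.
#'
#' @param name One of `"broadband"`, `"theta"`, `"alpha"`, `"beta"`.
#' @return A `ci_foi_band`: list with `name` and `range` (Hz interval).
#' @export
foi_band <- function(name = c("broadband", "theta", "alpha", "beta")) {
  name <- match.arg(name)
  range <- switch(name,
                  broadband = c(4, 25), theta = c(5, 8),
                  alpha = c(9, 13), beta = c(14, 24))
  structure(list(name = name, range = range), class = "ci_foi_band")
}

#' @rdname foi_band
#' @export
foi_names <- function() c("broadband", "theta", "alpha", "beta")

#' Hann-tapered power spectral density of one trial
#'
#' Demeans, linearly detrends and Hann-tapers the 65-sample series, then
#' reports one-sided power on the integer-Hz bins intersecting
#' `[fmin, fmax]`. A 1 s window gives exactly 1 Hz resolution, so the bins
#' are the DFT bins themselves (no zero padding). Power is normalised by the
#' taper energy (`fs * sum(w^2)`), with the factor 2 for the one-sided
#' spectrum; all downstream inference is scale-invariant.
#'
#' @param series Numeric vector (default length 65) or samples-by-trials
#'   matrix; each column is one trial.
#' @param sampling_rate Hz.
#' @param fmin,fmax Frequency range reported (Hz, inclusive).
#' @return For a vector input, a `ci_power_spectrum`: list with `freqs`,
#'   `power`, `level = "trial"`. For a matrix, a list with `freqs` and a
#'   bins-by-trials `power` matrix.
#' @export
trial_psd <- function(series, sampling_rate = 65, fmin = 4, fmax = 25) {
  if (is.matrix(series)) {
    n <- nrow(series)
    prep <- psd_prep(n, sampling_rate, fmin, fmax)
    x <- series - rep(colMeans(series), each = n)
    x <- x - prep$trend %*% (crossprod(prep$trend, x))
    X <- stats::mvfft(x * prep$taper)
    pw <- (Mod(X[prep$bins, , drop = FALSE])^2) * prep$scale
    return(list(freqs = prep$freqs, power = pw, level = "trial"))
  }
  if (length(series) < 8)
    stop("trial_psd: series too short", call. = FALSE)
  res <- trial_psd(matrix(series, ncol = 1), sampling_rate, fmin, fmax)
  structure(list(freqs = res$freqs, power = as.numeric(res$power),
                 level = "trial"), class = "ci_power_spectrum")
}

# Precomputed taper, orthonormal detrend basis, bin bookkeeping.
psd_prep <- function(n, fs, fmin, fmax) {
  taper <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))  # Hann
  tt <- seq_len(n) - (n + 1) / 2
  trend <- matrix(tt / sqrt(sum(tt^2)), ncol = 1)  # unit-norm linear basis
  freqs_all <- (seq_len(n) - 1) * fs / n
  bins <- which(freqs_all >= fmin - 1e-9 & freqs_all <= fmax + 1e-9 &
                  freqs_all <= fs / 2)
  # one-sided scaling: double every bin except DC (and Nyquist, if on-grid)
  dbl <- ifelse(freqs_all[bins] < 1e-9 | abs(freqs_all[bins] - fs / 2) < 1e-9,
                1, 2)
  list(taper = taper, trend = trend, bins = bins, freqs = freqs_all[bins],
       scale = dbl / (fs * sum(taper^2)))
}

#' Condition-averaged spectra
#'
#' Bin-wise arithmetic mean of trial spectra within each cue condition.
#'
#' @param spectra Output of [trial_psd()] on a matrix (fields `freqs`,
#'   `power` bins-by-trials).
#' @param labels Character/factor vector of per-trial cues
#'   (`"auditory"`/`"visual"`).
#' @return Named list of `ci_power_spectrum` objects, one per condition,
#'   with `level = "condition-average"`.
#' @export
condition_average <- function(spectra, labels) {
  pw <- spectra$power
  if (ncol(pw) != length(labels))
    stop("condition_average: one label per trial required", call. = FALSE)
  labels <- as.character(labels)
  out <- lapply(unique(labels), function(l) {
    idx <- labels == l
    if (!any(idx))
      stop("condition_average: condition '", l, "' has no trials",
           call. = FALSE)
    structure(list(freqs = spectra$freqs,
                   power = rowMeans(pw[, idx, drop = FALSE]),
                   level = "condition-average"),
              class = "ci_power_spectrum")
  })
  names(out) <- unique(labels)
  if (length(out) < 2)
    stop("condition_average: need trials from both conditions", call. = FALSE)
  out
}

#' Mean power over a frequency band
#'
#' Arithmetic mean of power over the band's integer-Hz bins (theta averages
#' bins 5, 6, 7 and 8 Hz).
#'
#' @param spectrum A `ci_power_spectrum`, or a list with `freqs` and a
#'   bins-by-trials `power` matrix (then a per-trial vector is returned).
#' @param band A [foi_band()] or band name.
#' @return Scalar (or per-trial vector) band power.
#' @export
band_average <- function(spectrum, band = foi_band("theta")) {
  if (is.character(band)) band <- foi_band(band)
  idx <- which(spectrum$freqs >= band$range[1] - 1e-9 &
                 spectrum$freqs <= band$range[2] + 1e-9)
  if (!length(idx))
    stop("band_average: band ", band$name, " has no bins in the spectrum",
         call. = FALSE)
  if (is.matrix(spectrum$power))
    colMeans(spectrum$power[idx, , drop = FALSE])
  else
    mean(spectrum$power[idx])
}

#' Moving-average smoothing for display
#'
#' Centred `n_points` moving average with shrinking windows at the edges.
#' Display only; never feeds any statistic.
#'
#' @param spectrum A `ci_power_spectrum`.
#' @param n_points Odd window length.
#' @return The smoothed spectrum.
#' @export
smooth_spectrum <- function(spectrum, n_points = 5L) {
  n_points <- as.integer(n_points)
  if (n_points < 1L || n_points %% 2L != 1L)
    stop("smooth_spectrum: n_points must be odd", call. = FALSE)
  p <- spectrum$power
  half <- n_points %/% 2L
  sm <- vapply(seq_along(p), function(i) {
    lo <- max(1L, i - half); hi <- min(length(p), i + half)
    mean(p[lo:hi])
  }, numeric(1))
  spectrum$power <- sm
  spectrum
}

#' Within-subject standard errors (Cousineau-Morey)
#'
#' Removes each subject's cross-condition mean (adding back the grand mean)
#' and scales the per-condition SEM of the normalised scores by the Morey
#' bias-correction factor `sqrt(C / (C - 1))`, `C` = number of conditions.
#'
#' @param band_powers Numeric matrix, subjects x conditions.
#' @return Named numeric vector of corrected per-condition SEMs.
#' @export
within_subject_sem <- function(band_powers) {
  band_powers <- as.matrix(band_powers)
  n <- nrow(band_powers); C <- ncol(band_powers)
  if (n < 2L) stop("within_subject_sem: need at least 2 subjects",
                   call. = FALSE)
  if (C < 2L) stop("within_subject_sem: need at least 2 conditions",
                   call. = FALSE)
  norm <- band_powers - rowMeans(band_powers) + mean(band_powers)
  sem <- apply(norm, 2, stats::sd) / sqrt(n)
  out <- sem * sqrt(C / (C - 1))
  names(out) <- colnames(band_powers)
  out
}

#' Per-subject condition band powers
#'
#' Convenience: trial spectra of a reconstructed session averaged to one
#' value per condition for a given band (mean over the band's bins and the
#' subject's trials in that condition).
#'
#' @param series_set A `ci_series_set` from [reconstruct_session()].
#' @param band A [foi_band()] or band name.
#' @return Named numeric vector `c(auditory = , visual = )`.
#' @export
subject_band_power <- function(series_set, band = foi_band("theta")) {
  stopifnot(inherits(series_set, "ci_series_set"))
  sp <- trial_psd(series_set$series, series_set$sampling_rate)
  bp <- band_average(sp, band)
  cue <- series_set$meta$cue
  c(auditory = mean(bp[cue == "auditory"]),
    visual = mean(bp[cue == "visual"]))
}

#' @export
print.ci_power_spectrum <- function(x, ...) {
  cat("<ci_power_spectrum> ", length(x$freqs), " bins ", min(x$freqs), "-",
      max(x$freqs), " Hz (", x$level, ")\n", sep = "")
  invisible(x)
}
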