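#' Band-pass filter specification
#'
#' Parameters of the linear-phase windowed-sinc FIR band-pass applied to the
#' reconstructed 65 Hz series. `order` is the filter order (number of taps
#' minus one); an even order gives an integer group delay so the one-pass
#' zero-phase application can compensate it exactly.
#'
#' @param low_cut,high_cut Passband edges in Hz.
#' @param order Filter order (424 -> 425 coefficients).
#' @param transition_width Nominal transition width in Hz (informational; the
#'   realised transition follows from the order and window shape).
#' @param window_shape Taper applied to the sinc kernel (`"hamming"`).
#' @return A `ci_filter_spec`.
#' @export
filter_spec <- function(low_cut = 4, high_cut = 25, order = 424L,
                        transition_width = 0.5, window_shape = "hamming") {
  if (low_cut <= 0 || high_cut <= low_cut)
    stop("filter_spec: need 0 < low_cut < high_cut", call. = FALSE)
  order <- as.integer(order)
  if (order < 2L || order %% 2L != 0L)
    stop("filter_spec: order must be a positive even integer", call. = FALSE)
  structure(list(low_cut = low_cut, high_cut = high_cut, order = order,
                 transition_width = transition_width,
                 window_shape = window_shape),
            class = "ci_filter_spec")
}

#' Reduce a raw windowed trial to one sample per window
#'
#' Discards the artifact-contaminated first `discard_n` samples of every
#' recording window and averages the remainder, yielding one voltage per
#' window; concatenating the window means gives the trial's 65-sample,
#' 65 Hz series.
#'
#' @param trial A `ci_raw_trial` with a window matrix, or a bare numeric
#'   matrix (`n_windows x samples_per_window`).
#' @param discard_n Number of leading samples discarded from every window.
#' @return Numeric vector of length `n_windows` (the unfiltered series).
#' @export
window_average <- function(trial, discard_n = 100L) {
  win <- if (is.matrix(trial)) trial else trial$windows
  if (is.null(win))
    stop("window_average: trial carries no window matrix ",
         "(generated with keep_windows = FALSE?)", call. = FALSE)
  discard_n <- as.integer(discard_n)
  if (discard_n < 0L || discard_n >= ncol(win))
    stop("window_average: discard_n must lie in [0, samples_per_window)",
         call. = FALSE)
  if (!all(is.finite(win)))
    stop("window_average: non-finite values in window matrix", call. = FALSE)
  rowMeans(win[, seq.int(discard_n + 1L, ncol(win)), drop = FALSE])
}

#' Per-trial series matrix of a session
#'
#' Applies [window_average()] to every trial (or takes the stored series for
#' memory-lean sessions) and returns them as a samples-by-trials matrix.
#'
#' @param session A `ci_session`.
#' @param discard_n Prefix samples to discard; for memory-lean sessions this
#'   must equal the config's `artifact_prefix_len` used at generation.
#' @return Numeric matrix `n_windows_per_trial x n_trials`.
#' @export
as_series_matrix <- function(session,
                             discard_n = session$config$artifact_prefix_len) {
  stopifnot(inherits(session, "ci_session"))
  vapply(session$trials, function(tr) {
    if (!is.null(tr$windows)) return(window_average(tr, discard_n))
    if (discard_n != session$config$artifact_prefix_len)
      stop("as_series_matrix: stored series used artifact_prefix_len = ",
           session$config$artifact_prefix_len, ", cannot re-average with ",
           "discard_n = ", discard_n, call. = FALSE)
    tr$series
  }, numeric(session$config$n_windows_per_trial))
}

#' Design the windowed-sinc band-pass kernel
#'
#' Hamming-windowed sinc FIR band-pass (via [signal::fir1()]), `order + 1`
#' symmetric coefficients, linear phase, approximately unit passband gain.
#'
#' @param spec A [filter_spec()].
#' @param sampling_rate Series sampling rate in Hz.
#' @return Numeric vector of `order + 1` tap coefficients.
#' @export
design_bandpass <- function(spec = filter_spec(), sampling_rate = 65) {
  stopifnot(inherits(spec, "ci_filter_spec"))
  nyq <- sampling_rate / 2
  if (spec$high_cut >= nyq)
    stop("design_bandpass: high_cut must lie below the Nyquist frequency (",
         nyq, " Hz)", call. = FALSE)
  w <- c(spec$low_cut, spec$high_cut) / nyq
  taps <- signal::fir1(spec$order, w, type = "pass",
                       window = signal::hamming(spec$order + 1L))
  as.numeric(taps)
}

#' Apply a linear-phase FIR filter with zero net phase
#'
#' One forward pass of the symmetric kernel with exact group-delay
#' compensation. Because the kernel (425 taps by default) is much longer than
#' a 65-sample trial, the series is first extended by the chosen padding and
#' truncated back to its original length afterwards.
#'
#' @param series Numeric vector (one trial) or samples-by-trials matrix.
#' @param kernel Odd-length symmetric FIR coefficients from
#'   [design_bandpass()].
#' @param pad_mode `"mirror"` (reflection without repeating the edge sample,
#'   applied repeatedly until the pad is long enough), or `"zero"`.
#' @return Filtered series with the same shape as the input.
#' @export
apply_zerophase <- function(series, kernel, pad_mode = c("mirror", "zero")) {
  pad_mode <- match.arg(pad_mode)
  if (is.matrix(series))
    return(apply(series, 2, apply_zerophase, kernel = kernel,
                 pad_mode = pad_mode))
  n <- length(series)
  lk <- length(kernel)
  if (lk %% 2L != 1L)
    stop("apply_zerophase: kernel must have odd length (even order)",
         call. = FALSE)
  half <- (lk - 1L) %/% 2L
  pad <- half + lk  # generous margin so the convolution core covers the trial
  ext <- pad_series(series, pad, pad_mode)
  if (length(ext) <= lk)
    stop("apply_zerophase: kernel longer than padded signal", call. = FALSE)
  full <- stats::convolve(ext, rev(kernel), type = "open")
  # sample i of the input sits at ext position pad + i; after full
  # convolution its zero-delay image sits at pad + i + half
  full[pad + half + seq_len(n)]
}

# Mirror (reflect about the edge sample, edge not repeated) or zero padding.
pad_series <- function(x, pad, mode) {
  n <- length(x)
  if (mode == "zero") return(c(numeric(pad), x, numeric(pad)))
  if (n < 2L) stop("pad_series: need at least 2 samples to mirror",
                   call. = FALSE)
  # whole-axis reflection indices: period 2(n-1), edge samples not doubled
  idx <- seq.int(-pad + 1L, n + pad)
  m <- (idx - 1L) %% (2L * (n - 1L))
  m <- ifelse(m >= n, 2L * (n - 1L) - m, m)
  x[m + 1L]
}

#' Retain only correct-response trials
#'
#' @param session A `ci_session` whose trials carry `response_correct` flags.
#' @return The session containing only the correct trials, order preserved.
#' @export
select_correct_trials <- function(session) {
  stopifnot(inherits(session, "ci_session"))
  ok <- vapply(session$trials, function(tr) isTRUE(tr$response_correct),
               logical(1))
  if (any(vapply(session$trials,
                 function(tr) is.na(tr$response_correct), logical(1))))
    stop("select_correct_trials: response flags missing; run ",
         "simulate_behavior() first", call. = FALSE)
  if (!any(ok)) warning("select_correct_trials: no correct trials retained")
  session$trials <- session$trials[ok]
  session$ground_truth <- session$ground_truth[ok, , drop = FALSE]
  session
}

#' Reconstruct a session into per-trial 65 Hz series
#'
#' Runs the full preprocessing: optional correct-trial selection, per-window
#' prefix discard and averaging, and (optionally) the one-pass zero-phase
#' band-pass.
#'
#' @param session A `ci_session`.
#' @param discard_n Prefix samples discarded per window.
#' @param filter Apply the band-pass (`TRUE`) or leave series raw. Spectral
#'   analysis on 4-25 Hz is insensitive to this choice since the band lies
#'   inside the passband.
#' @param spec A [filter_spec()] used when `filter = TRUE`.
#' @param correct_only Keep only correct-response trials first.
#' @return A `ci_series_set`: list with `series`
#'   (`n_samples x n_trials` matrix), `meta` (trial metadata data frame),
#'   `sampling_rate`, `filtered`.
#' @export
reconstruct_session <- function(session,
                                discard_n = session$config$artifact_prefix_len,
                                filter = FALSE,
                                spec = filter_spec(),
                                correct_only = FALSE) {
  stopifnot(inherits(session, "ci_session"))
  if (correct_only) session <- select_correct_trials(session)
  fs <- effective_sampling_rate(session$config)
  series <- as_series_matrix(session, discard_n = discard_n)
  if (filter) {
    kernel <- design_bandpass(spec, fs)
    series <- apply_zerophase(series, kernel)
  }
  structure(list(series = series, meta = session_metadata(session),
                 sampling_rate = fs, filtered = filter,
                 subject_id = session$subject_id),
            class = "ci_series_set")
}

#' @export
print.ci_series_set <- function(x, ...) {
  cat("<ci_series_set> ", ncol(x$series), " trials x ", nrow(x$series),
      " samples at ", x$sampling_rate, " Hz (",
      if (x$filtered) "band-passed" else "unfiltered", ")\n", sep = "")
  invisible(x)
}
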