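#' Generate a synthetic recording session
#'
#' Simulates one subject's complete session of the crossmodal attention
#' experiment: the block design with exact per-block cue counts and
#' independently drawn visual/auditory oddballs, and for each trial the raw
#' windowed recording of the 1 s silent cue-target interval. Each trial's
#' latent signal is a continuous process (broadband Gaussian background plus
#' a theta-band component whose amplitude depends on the cued modality),
#' sampled into `n_windows_per_trial` recording windows of
#' `samples_per_window` points each. Each window additionally receives an
#' independent Gaussian offset (the acquisition chain's offset noise) and a
#' deterministic exponentially decaying artifact over its first
#' `artifact_prefix_len` samples; the whole trial is shifted by a uniform
#' start jitter.
#'
#' @param config A [session_config()].
#' @param effect An [effect_spec()].
#' @param subject_id Identifier stored on every trial.
#' @param seed Integer seed; identical `(config, effect, seed)` give
#'   bit-identical sessions. `NULL` uses the current RNG state.
#' @param keep_windows If `TRUE` (default) every trial retains its full
#'   `n_windows_per_trial x samples_per_window` window matrix (about 0.5 GB
#'   for the default design). If `FALSE`, each trial's windows are reduced to
#'   the 65-sample series immediately after generation using the standard
#'   prefix-discard window average (`discard_n = artifact_prefix_len`), and
#'   only the series is stored; the result is sample-for-sample identical to
#'   running [window_average()] on the retained windows.
#' @return A `ci_session`: list with `config`, `effect`, `subject_id`,
#'   `subject_gain` (the realised attend-auditory amplitude gain for this
#'   subject), `trials` (list of `ci_raw_trial`), and `ground_truth`
#'   (data frame of per-trial latent theta amplitudes).
#' @export
generate_session <- function(config = session_config(),
                             effect = effect_spec(),
                             subject_id = "S01",
                             seed = NULL,
                             keep_windows = TRUE) {
  validate_session_config(config)
  stopifnot(inherits(effect, "ci_effect_spec"))
  if (!is.null(seed)) set.seed(as.integer(seed))

  subject_gain <- effect$attend_auditory_gain
  if (effect$per_subject_gain_sd > 0)
    subject_gain <- subject_gain * exp(stats::rnorm(1, 0,
                                                    effect$per_subject_gain_sd))

  meta <- build_design(config, subject_id)
  n_trials <- nrow(meta)
  meta$start_jitter <- stats::runif(n_trials, 0, config$start_jitter_max)

  amp <- ifelse(meta$cue == "auditory",
                effect$base_theta_amplitude * subject_gain,
                effect$base_theta_amplitude)

  period_ms <- config$window_duration + config$reset_duration
  spw <- config$samples_per_window
  nw <- config$n_windows_per_trial
  dt_ms <- config$window_duration / spw
  # latent span covers the longest-jittered trial plus one window
  span_ms <- config$start_jitter_max + nw * period_ms + config$window_duration
  n_lat <- ceiling(span_ms / 1000 * config$latent_rate) + 2L
  t_lat <- (seq_len(n_lat) - 1) / config$latent_rate * 1000  # ms

  # sample times of every window sample relative to trial start (ms)
  base_times <- rep((seq_len(nw) - 1) * period_ms, each = spw) +
    rep((seq_len(spw) - 1) * dt_ms, times = nw)
  artifact <- artifact_waveform(config)

  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    latent <- latent_trial_signal(n_lat, config$latent_rate, effect$theta_band,
                                  amp[i], effect$broadband_noise_sd)
    x <- stats::approx(t_lat, latent, xout = meta$start_jitter[i] + base_times,
                       rule = 2)$y
    win <- matrix(x, nrow = nw, ncol = spw, byrow = TRUE)
    if (config$offset_sd > 0)
      win <- win + stats::rnorm(nw, 0, config$offset_sd)
    else
      stats::rnorm(nw)  # keep RNG stream aligned across offset settings
    if (config$artifact_prefix_len > 0L)
      win[, seq_len(config$artifact_prefix_len)] <-
        win[, seq_len(config$artifact_prefix_len)] +
        rep(artifact, each = nw)
    tr <- c(as.list(meta[i, , drop = FALSE]), list(windows = NULL,
                                                   series = NULL))
    if (keep_windows) {
      tr$windows <- win
    } else {
      keep <- seq.int(config$artifact_prefix_len + 1L, spw)
      tr$series <- rowMeans(win[, keep, drop = FALSE])
    }
    class(tr) <- "ci_raw_trial"
    trials[[i]] <- tr
  }

  structure(list(config = config, effect = effect, subject_id = subject_id,
                 subject_gain = subject_gain, trials = trials,
                 ground_truth = data.frame(trial_index = meta$trial_index,
                                           cue = meta$cue,
                                           theta_amplitude = amp)),
            class = "ci_session")
}

# Block design with exact per-block cue counts and independent oddball draws.
build_design <- function(config, subject_id) {
  blocks <- lapply(seq_len(config$n_blocks), function(b) {
    cues <- sample(c(rep("auditory", config$n_auditory_cues_per_block),
                     rep("visual", config$n_visual_cues_per_block)))
    vis_odd <- logical(config$trials_per_block)
    vis_odd[sample.int(config$trials_per_block,
                       config$n_visual_oddballs_per_block)] <- TRUE
    aud_odd <- logical(config$trials_per_block)
    aud_odd[sample.int(config$trials_per_block,
                       config$n_auditory_oddballs_per_block)] <- TRUE
    data.frame(subject_id = subject_id, block = b,
               trial_in_block = seq_len(config$trials_per_block),
               cue = cues, is_visual_oddball = vis_odd,
               is_auditory_oddball = aud_odd,
               response_correct = NA)
  })
  meta <- do.call(rbind, blocks)
  meta$trial_index <- seq_len(nrow(meta))
  meta
}

# Latent 1 s process: broadband white Gaussian background plus narrow-band
# Gaussian noise confined to the theta band, scaled to the requested SD.
latent_trial_signal <- function(n, rate, band, theta_amplitude, broadband_sd) {
  freqs <- (seq_len(n) - 1) * rate / n
  freqs <- pmin(freqs, rate - freqs)             # two-sided frequency axis
  z <- stats::rnorm(n)
  Z <- stats::fft(z)
  Z[freqs < band[1] | freqs > band[2]] <- 0+0i
  theta <- Re(stats::fft(Z, inverse = TRUE)) / n
  s <- stats::sd(theta)
  if (s > 0) theta <- theta * (theta_amplitude / s)
  broad <- if (broadband_sd > 0) stats::rnorm(n, 0, broadband_sd) else {
    stats::rnorm(n)  # consume stream for alignment
    numeric(n)
  }
  theta + broad
}

# Deterministic decaying filter-artifact prefix (one shape shared by all
# windows; the real system's artifact shape is unknown, only its removal).
artifact_waveform <- function(config) {
  p <- config$artifact_prefix_len
  if (p == 0L) return(numeric(0))
  tau <- max(p / 5, 1)
  config$artifact_amplitude * exp(-(seq_len(p) - 1) / tau)
}

#' Simulate behavioural responses
#'
#' Marks every trial correct independently with the given probability.
#'
#' @param session A `ci_session`.
#' @param accuracy Probability of a correct response in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return The session with `response_correct` filled in on every trial.
#' @export
simulate_behavior <- function(session,
                              accuracy = session$config$behavior_accuracy,
                              seed = NULL) {
  stopifnot(inherits(session, "ci_session"))
  if (accuracy < 0 || accuracy > 1)
    stop("simulate_behavior: accuracy must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ok <- stats::runif(length(session$trials)) < accuracy
  for (i in seq_along(session$trials))
    session$trials[[i]]$response_correct <- ok[i]
  session
}

#' Trial metadata table
#'
#' @param session A `ci_session`.
#' @return A data frame with one row per trial (subject, block, trial index,
#'   cue, oddball flags, response correctness, start jitter).
#' @export
session_metadata <- function(session) {
  stopifnot(inherits(session, "ci_session"))
  cols <- c("subject_id", "block", "trial_in_block", "trial_index", "cue",
            "is_visual_oddball", "is_auditory_oddball", "response_correct",
            "start_jitter")
  do.call(rbind, lapply(session$trials, function(tr)
    as.data.frame(tr[cols], stringsAsFactors = FALSE)))
}

#' Generate a companion EEG recording
#'
#' Builds a multichannel surrogate EEG recorded simultaneously with the CI
#' series, used by the volume-conduction check. The latent cortical source of
#' each trial is the z-scored CI series of that trial; channel `c` is
#' independent Gaussian sensor noise plus `mixing[c]` times that source, so
#' `mixing = 0` everywhere yields EEG sharing no instantaneous source with
#' the CI channel, while `mixing[c] = 1` with `noise_sd = 0` reproduces the
#' source exactly.
#'
#' @param session A `ci_session`.
#' @param n_channels Number of EEG channels.
#' @param mixing Numeric vector of length `n_channels`: per-channel leakage
#'   coefficient of the shared source (0 = no volume conduction).
#' @param noise_sd Per-channel sensor-noise SD.
#' @param discard_n Prefix samples discarded when reconstructing the CI
#'   series from raw windows (defaults to the config's artifact prefix).
#' @param seed Optional integer seed.
#' @return A `ci_eeg_companion`: list with `channels` (array
#'   `[n_samples, n_channels, n_trials]`), `source` (matrix
#'   `n_samples x n_trials`), `mixing`, `noise_sd`.
#' @export
generate_eeg_companion <- function(session, n_channels = 55L,
                                   mixing = rep(0, n_channels),
                                   noise_sd = 1,
                                   discard_n = session$config$artifact_prefix_len,
                                   seed = NULL) {
  stopifnot(inherits(session, "ci_session"))
  if (length(mixing) != n_channels)
    stop("generate_eeg_companion: length(mixing) must equal n_channels",
         call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ci <- as_series_matrix(session, discard_n = discard_n)
  n_samp <- nrow(ci)
  n_trials <- ncol(ci)
  src <- apply(ci, 2, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  chan <- array(stats::rnorm(n_samp * n_channels * n_trials, 0, noise_sd),
                dim = c(n_samp, n_channels, n_trials))
  for (c_i in seq_len(n_channels))
    if (mixing[c_i] != 0)
      chan[, c_i, ] <- chan[, c_i, ] + mixing[c_i] * src
  structure(list(channels = chan, source = src, mixing = mixing,
                 noise_sd = noise_sd, subject_id = session$subject_id),
            class = "ci_eeg_companion")
}

#' @export
print.ci_session <- function(x, ...) {
  n_aud <- sum(vapply(x$trials, function(t) t$cue == "auditory", logical(1)))
  cat("<ci_session> subject ", x$subject_id, ": ", length(x$trials),
      " trials (", n_aud, " auditory / ", length(x$trials) - n_aud,
      " visual cues), windows ",
      if (is.null(x$trials[[1]]$windows)) "reduced to series" else "retained",
      "\n", sep = "")
  invisible(x)
}
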