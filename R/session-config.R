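#' Session configuration for the windowed-recording attention experiment
#'
#' Describes the experimental design and acquisition scheme of a cochlear
#' implant (CI) recording session: a crossmodal attention task run in blocks
#' of trials, each trial carrying a 1 s silent cue-target interval during
#' which the implant records short windows of auditory-nerve activity
#' separated by reset periods.
#'
#' @param n_blocks Number of blocks per session.
#' @param trials_per_block Trials in each block.
#' @param n_auditory_cues_per_block,n_visual_cues_per_block Per-block counts
#'   of attend-auditory and attend-visual cues; they must sum to
#'   `trials_per_block`.
#' @param n_visual_oddballs_per_block,n_auditory_oddballs_per_block Per-block
#'   counts of oddball trials, drawn independently for the two modalities
#'   (a trial can be both).
#' @param window_duration Recording-window length in ms.
#' @param reset_duration Reset period between windows in ms.
#' @param samples_per_window Samples digitised inside each recording window.
#' @param n_windows_per_trial Number of recording windows per trial.
#' @param offset_sd SD (mV) of the Gaussian offset added independently to
#'   each recording window by the acquisition chain.
#' @param start_jitter_max Maximum trial-start jitter in ms (uniform on
#'   `[0, start_jitter_max]`).
#' @param artifact_prefix_len Number of samples at the start of each window
#'   contaminated by the acquisition filter artifact.
#' @param artifact_amplitude Peak amplitude (mV) of the simulated decaying
#'   artifact written over the prefix samples.
#' @param behavior_accuracy Probability of a correct behavioural response.
#' @param latent_rate Sampling rate (Hz) at which the latent 1 s neural
#'   process is synthesised before being sampled into recording windows. The
#'   latent signal lives below 30 Hz, so any rate comfortably above 100 Hz
#'   gives numerically equivalent window averages; the default oversamples
#'   the 65 Hz effective rate by 32x.
#'
#' @return An object of class `ci_session_config` (a validated list).
#' @details The effective sampling rate of the reconstructed series is
#'   `1000 / (window_duration + reset_duration)` Hz (65 Hz under the
#'   defaults), and the discarded prefix spans
#'   `artifact_prefix_len * window_duration / samples_per_window` ms.
#'   See [design_summary()] for these derived constants.
#' @export
session_config <- function(n_blocks = 6L,
                           trials_per_block = 85L,
                           n_auditory_cues_per_block = 43L,
                           n_visual_cues_per_block = 42L,
                           n_visual_oddballs_per_block = 8L,
                           n_auditory_oddballs_per_block = 8L,
                           window_duration = 1.7,
                           reset_duration = 13.68,
                           samples_per_window = 2048L,
                           n_windows_per_trial = 65L,
                           offset_sd = 0.4,
                           start_jitter_max = 27,
                           artifact_prefix_len = 100L,
                           artifact_amplitude = 1,
                           behavior_accuracy = 0.96,
                           latent_rate = 2080) {
  cfg <- list(
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    n_auditory_cues_per_block = as.integer(n_auditory_cues_per_block),
    n_visual_cues_per_block = as.integer(n_visual_cues_per_block),
    n_visual_oddballs_per_block = as.integer(n_visual_oddballs_per_block),
    n_auditory_oddballs_per_block = as.integer(n_auditory_oddballs_per_block),
    window_duration = window_duration,
    reset_duration = reset_duration,
    samples_per_window = as.integer(samples_per_window),
    n_windows_per_trial = as.integer(n_windows_per_trial),
    offset_sd = offset_sd,
    start_jitter_max = start_jitter_max,
    artifact_prefix_len = as.integer(artifact_prefix_len),
    artifact_amplitude = artifact_amplitude,
    behavior_accuracy = behavior_accuracy,
    latent_rate = latent_rate
  )
  class(cfg) <- "ci_session_config"
  validate_session_config(cfg)
  cfg
}

validate_session_config <- function(cfg) {
  counts <- c("n_blocks", "trials_per_block", "n_auditory_cues_per_block",
              "n_visual_cues_per_block", "samples_per_window",
              "n_windows_per_trial")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] <= 0L)
      stop("session_config: '", f, "' must be a positive count", call. = FALSE)
  }
  for (f in c("n_visual_oddballs_per_block", "n_auditory_oddballs_per_block",
              "artifact_prefix_len")) {
    if (cfg[[f]] < 0L)
      stop("session_config: '", f, "' must be non-negative", call. = FALSE)
  }
  if (cfg$n_auditory_cues_per_block + cfg$n_visual_cues_per_block !=
      cfg$trials_per_block)
    stop("session_config: auditory + visual cues per block (",
         cfg$n_auditory_cues_per_block, " + ", cfg$n_visual_cues_per_block,
         ") must equal trials_per_block (", cfg$trials_per_block, ")",
         call. = FALSE)
  if (cfg$n_visual_oddballs_per_block > cfg$trials_per_block ||
      cfg$n_auditory_oddballs_per_block > cfg$trials_per_block)
    stop("session_config: oddball counts cannot exceed trials_per_block",
         call. = FALSE)
  if (cfg$window_duration <= 0 || cfg$reset_duration < 0)
    stop("session_config: window/reset durations must be positive",
         call. = FALSE)
  if (cfg$n_windows_per_trial * (cfg$window_duration + cfg$reset_duration) <
      999)
    stop("session_config: windows must span at least 999 ms ",
         "(n_windows_per_trial * (window_duration + reset_duration) too short)",
         call. = FALSE)
  if (cfg$artifact_prefix_len >= cfg$samples_per_window)
    stop("session_config: artifact_prefix_len must be smaller than ",
         "samples_per_window", call. = FALSE)
  if (cfg$offset_sd < 0)
    stop("session_config: offset_sd must be non-negative", call. = FALSE)
  if (cfg$behavior_accuracy < 0 || cfg$behavior_accuracy > 1)
    stop("session_config: behavior_accuracy must lie in [0, 1]", call. = FALSE)
  if (cfg$latent_rate < 4 * effective_sampling_rate(cfg))
    stop("session_config: latent_rate must oversample the effective ",
         "sampling rate at least 4x", call. = FALSE)
  invisible(cfg)
}

#' Effect specification for the synthetic attention modulation
#'
#' Parameters of the latent neural signal injected into synthetic sessions:
#' broadband background activity plus a theta-band (5-8 Hz by default)
#' component whose amplitude is multiplied by `attend_auditory_gain` on
#' attend-auditory trials. The theta component is amplitude-modulated
#' narrow-band Gaussian noise (white noise band-limited to `theta_band`),
#' not a pure sinusoid, so simulated spectra show a broad, peakless shape
#' like real prestimulus CI spectra.
#'
#' @param theta_band Two-element frequency interval (Hz) of the modulated
#'   component.
#' @param base_theta_amplitude Target SD (mV) of the theta component on
#'   attend-visual trials.
#' @param attend_auditory_gain Multiplicative amplitude gain applied on
#'   attend-auditory trials; 1 means no attentional effect.
#' @param broadband_noise_sd SD (mV) of the broadband latent background.
#' @param per_subject_gain_sd SD of a log-normal per-subject jitter on
#'   `attend_auditory_gain` (0 disables subject heterogeneity).
#' @return An object of class `ci_effect_spec`.
#' @export
effect_spec <- function(theta_band = c(5, 8),
                        base_theta_amplitude = 0.1,
                        attend_auditory_gain = 1.3,
                        broadband_noise_sd = 0.1,
                        per_subject_gain_sd = 0) {
  if (length(theta_band) != 2L || theta_band[1] >= theta_band[2])
    stop("effect_spec: theta_band must be an increasing frequency interval",
         call. = FALSE)
  vals <- c(base_theta_amplitude, attend_auditory_gain, broadband_noise_sd,
            per_subject_gain_sd)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("effect_spec: amplitudes, gains and SDs must be finite and ",
         "non-negative", call. = FALSE)
  structure(list(theta_band = as.numeric(theta_band),
                 base_theta_amplitude = base_theta_amplitude,
                 attend_auditory_gain = attend_auditory_gain,
                 broadband_noise_sd = broadband_noise_sd,
                 per_subject_gain_sd = per_subject_gain_sd),
            class = "ci_effect_spec")
}

#' Effective sampling rate of the reconstructed series
#'
#' One sample per recording window: `1000 / (window + reset)` Hz, rounded to
#' the nearest integer Hz (65 Hz for 1.7 ms windows with 13.68 ms resets).
#'
#' @param config A [session_config()].
#' @return Sampling rate in Hz.
#' @export
effective_sampling_rate <- function(config) {
  as.integer(round(1000 / (config$window_duration + config$reset_duration)))
}

#' Derived design constants
#'
#' Arithmetic consequences of the acquisition scheme: the effective sampling
#' rate, the temporal span of the discarded artifact prefix, the in-window
#' digitisation rate, and total/per-block trial counts.
#'
#' @param config A [session_config()].
#' @return A list with `sampling_rate_hz`, `discard_ms` (duration of the
#'   discarded prefix), `window_sample_rate_hz`, `n_trials`,
#'   `n_auditory_cues_per_block`, `n_visual_oddballs_per_block`,
#'   `samples_per_window`, `trial_duration_ms`.
#' @export
design_summary <- function(config) {
  stopifnot(inherits(config, "ci_session_config"))
  window_rate <- config$samples_per_window / (config$window_duration / 1000)
  list(
    sampling_rate_hz = effective_sampling_rate(config),
    discard_ms = round(config$artifact_prefix_len *
                         config$window_duration / config$samples_per_window, 3),
    window_sample_rate_hz = window_rate,
    n_trials = config$n_blocks * config$trials_per_block,
    n_auditory_cues_per_block = config$n_auditory_cues_per_block,
    n_visual_oddballs_per_block = config$n_visual_oddballs_per_block,
    samples_per_window = config$samples_per_window,
    trial_duration_ms = config$n_windows_per_trial *
      (config$window_duration + config$reset_duration)
  )
}

#' @export
print.ci_session_config <- function(x, ...) {
  d <- design_summary(x)
  cat("<ci_session_config>\n",
      "  ", x$n_blocks, " blocks x ", x$trials_per_block, " trials (",
      x$n_auditory_cues_per_block, " auditory / ",
      x$n_visual_cues_per_block, " visual cues, ",
      x$n_auditory_oddballs_per_block, "+", x$n_visual_oddballs_per_block,
      " oddballs per block)\n",
      "  windows: ", x$n_windows_per_trial, " x ", x$samples_per_window,
      " samples (", x$window_duration, " ms + ", x$reset_duration,
      " ms reset) -> ", d$sampling_rate_hz, " Hz\n",
      "  offset SD ", x$offset_sd, " mV, jitter <= ", x$start_jitter_max,
      " ms, artifact prefix ", x$artifact_prefix_len, " samples\n", sep = "")
  invisible(x)
}

#' @export
print.ci_effect_spec <- function(x, ...) {
  cat("<ci_effect_spec> theta ", x$theta_band[1], "-", x$theta_band[2],
      " Hz, base amplitude ", x$base_theta_amplitude,
      " mV, attend-auditory gain ", x$attend_auditory_gain,
      ", broadband SD ", x$broadband_noise_sd,
      ", subject gain SD ", x$per_subject_gain_sd, "\n", sep = "")
  invisible(x)
}
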