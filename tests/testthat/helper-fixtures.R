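# Reduced-fidelity session configurations for fast simulation-based tests.
# The acquisition noise parameters (offset SD, jitter) stay at study values;
# only problem sizes (blocks, trials, in-window samples, latent rate) shrink.

fast_config <- function(n_blocks = 2L, trials_per_block = 30L,
                        n_aud = 15L, n_vis = 15L, oddballs = 3L,
                        samples_per_window = 8L, artifact_prefix_len = 2L,
                        latent_rate = 260) {
  session_config(n_blocks = n_blocks, trials_per_block = trials_per_block,
                 n_auditory_cues_per_block = n_aud,
                 n_visual_cues_per_block = n_vis,
                 n_visual_oddballs_per_block = oddballs,
                 n_auditory_oddballs_per_block = oddballs,
                 samples_per_window = samples_per_window,
                 artifact_prefix_len = artifact_prefix_len,
                 latent_rate = latent_rate)
}

null_effect <- function() effect_spec(attend_auditory_gain = 1,
                                      per_subject_gain_sd = 0)

# One subject's per-condition theta band power through the full pipeline:
# generate -> behaviour -> (select) -> window-average -> PSD -> band mean.
subject_theta_pair <- function(cfg, eff, seed, correct_only = FALSE,
                               band = "theta") {
  ses <- generate_session(cfg, eff, seed = seed, keep_windows = FALSE)
  ses <- simulate_behavior(ses, seed = seed + 7L)
  rec <- reconstruct_session(ses, correct_only = correct_only)
  sp <- trial_psd(rec$series, effective_sampling_rate(cfg))
  bp <- band_average(sp, band)
  cue <- rec$meta$cue
  c(auditory = mean(bp[cue == "auditory"]), visual = mean(bp[cue == "visual"]))
}

# ---- independent brute-force oracles (deliberately naive implementations) --

# window mean by explicit double loop
oracle_window_mean <- function(win, discard_n) {
  out <- numeric(nrow(win))
  for (i in seq_len(nrow(win))) {
    acc <- 0
    cnt <- 0
    for (j in seq.int(discard_n + 1L, ncol(win))) {
      acc <- acc + win[i, j]
      cnt <- cnt + 1
    }
    out[i] <- acc / cnt
  }
  out
}

# tapered periodogram by direct DFT summation under the documented
# convention: demean, least-squares linear detrend, symmetric Hann taper,
# one-sided taper-energy normalisation
oracle_psd <- function(x, fs, fmin = 4, fmax = 25) {
  n <- length(x)
  x <- x - mean(x)
  tt <- seq_len(n)
  fit <- lm(x ~ tt)
  x <- residuals(fit)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  xw <- x * w
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- which(freqs >= fmin & freqs <= fmax & freqs <= fs / 2)
  pw <- sapply(keep, function(k) {
    f <- freqs[k]
    re <- sum(xw * cos(-2 * pi * (k - 1) * (seq_len(n) - 1) / n))
    im <- sum(xw * sin(-2 * pi * (k - 1) * (seq_len(n) - 1) / n))
    dbl <- if (f < 1e-9 || abs(f - fs / 2) < 1e-9) 1 else 2
    dbl * (re^2 + im^2) / (fs * sum(w^2))
  })
  list(freqs = freqs[keep], power = pw)
}

# exact one-tailed sign-flip p by full enumeration of the paired t statistic
oracle_signflip_p <- function(d) {
  n <- length(d)
  t_of <- function(v) mean(v) / (sd(v) / sqrt(length(v)))
  t_obs <- t_of(d)
  count <- 0L
  for (code in 0:(2^n - 1)) {
    s <- ifelse(bitwAnd(code, 2^(0:(n - 1))) > 0, 1, -1)
    if (t_of(d * s) >= t_obs - 1e-12) count <- count + 1L
  }
  count / 2^n
}

# kNN by explicit distance sort, lowest-index tie-break
oracle_knn <- function(train_x, train_y, test_x, k) {
  train_y <- factor(train_y)
  preds <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    d <- sqrt(rowSums((train_x - matrix(test_x[i, ], nrow(train_x),
                                        ncol(train_x), byrow = TRUE))^2))
    nb <- order(d)[seq_len(k)]
    tab <- table(train_y[nb])
    preds[i] <- names(tab)[which.max(tab)]
  }
  factor(preds, levels = levels(train_y))
}
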