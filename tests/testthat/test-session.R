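test_that("generated sessions conserve the block design exactly", {
  cfg <- fast_config()
  ses <- generate_session(cfg, null_effect(), seed = 11)
  md <- session_metadata(ses)
  expect_equal(nrow(md), cfg$n_blocks * cfg$trials_per_block)
  for (b in seq_len(cfg$n_blocks)) {
    blk <- md[md$block == b, ]
    expect_equal(sum(blk$cue == "auditory"), cfg$n_auditory_cues_per_block)
    expect_equal(sum(blk$cue == "visual"), cfg$n_visual_cues_per_block)
    expect_equal(sum(blk$is_visual_oddball), cfg$n_visual_oddballs_per_block)
    expect_equal(sum(blk$is_auditory_oddball),
                 cfg$n_auditory_oddballs_per_block)
  }
  # oddballs drawn independently: joint oddballs occur across many blocks
  cfg2 <- fast_config(n_blocks = 30L, trials_per_block = 10L, n_aud = 5L,
                      n_vis = 5L, oddballs = 4L)
  md2 <- session_metadata(generate_session(cfg2, null_effect(), seed = 3,
                                           keep_windows = FALSE))
  expect_gt(sum(md2$is_visual_oddball & md2$is_auditory_oddball), 0)
})

test_that("window matrices have the configured shape and finite values", {
  cfg <- fast_config()
  ses <- generate_session(cfg, effect_spec(), seed = 5)
  win <- ses$trials[[1]]$windows
  expect_equal(dim(win), c(cfg$n_windows_per_trial, cfg$samples_per_window))
  expect_true(all(is.finite(win)))
  jit <- session_metadata(ses)$start_jitter
  expect_true(all(jit >= 0 & jit <= cfg$start_jitter_max))
})

test_that("identical seeds reproduce sessions bit-identically, different seeds differ", {
  cfg <- fast_config()
  a <- generate_session(cfg, effect_spec(), seed = 99)
  b <- generate_session(cfg, effect_spec(), seed = 99)
  expect_identical(a, b)
  c <- generate_session(cfg, effect_spec(), seed = 100)
  expect_false(identical(a$trials[[1]]$windows, c$trials[[1]]$windows))
})

test_that("memory-lean generation equals prefix-discard averaging of the raw windows", {
  cfg <- fast_config()
  full <- generate_session(cfg, effect_spec(), seed = 21)
  lean <- generate_session(cfg, effect_spec(), seed = 21,
                           keep_windows = FALSE)
  expect_equal(as_series_matrix(full), as_series_matrix(lean),
               tolerance = 0)
  # re-averaging a lean session with a different prefix is refused
  expect_error(as_series_matrix(lean, discard_n = 0), "artifact_prefix_len")
})

test_that("unit attend gain yields identical latent theta amplitudes across cues", {
  cfg <- fast_config()
  eff <- effect_spec(attend_auditory_gain = 1, broadband_noise_sd = 0,
                     per_subject_gain_sd = 0)
  cfg$offset_sd <- 0
  ses <- generate_session(cfg, eff, seed = 8, keep_windows = FALSE)
  gt <- ses$ground_truth
  expect_equal(unique(gt$theta_amplitude[gt$cue == "auditory"]),
               unique(gt$theta_amplitude[gt$cue == "visual"]))
  # and the measured condition band-power contrast is small relative to level
  pair <- subject_theta_pair(cfg, eff, seed = 8)
  expect_lt(abs(pair["auditory"] - pair["visual"]) / mean(pair), 0.5)
})

test_that("measured theta contrast grows monotonically with the attend gain", {
  cfg <- fast_config(trials_per_block = 40L, n_aud = 20L, n_vis = 20L)
  gains <- c(1, 1.4, 1.8)
  contrast <- sapply(gains, function(g) {
    eff <- effect_spec(attend_auditory_gain = g, per_subject_gain_sd = 0)
    mean(sapply(1:6, function(s) {
      p <- subject_theta_pair(cfg, eff, seed = 400 + s)
      p["auditory"] - p["visual"]
    }))
  })
  expect_true(all(diff(contrast) > 0))
})

test_that("behavioural simulation matches its binomial contract", {
  cfg <- fast_config(n_blocks = 6L, trials_per_block = 85L, n_aud = 43L,
                     n_vis = 42L, oddballs = 8L)
  ses <- generate_session(cfg, null_effect(), seed = 77,
                          keep_windows = FALSE)
  all_correct <- simulate_behavior(ses, accuracy = 1, seed = 1)
  expect_true(all(session_metadata(all_correct)$response_correct))
  expect_equal(sum(session_metadata(all_correct)$response_correct), 510)
  expect_error(simulate_behavior(ses, accuracy = 1.2), "accuracy")
  # mean correct count over 1000 draws is close to 0.96 * 510 = 489.6
  counts <- sapply(1:1000, function(i)
    sum(session_metadata(simulate_behavior(ses, 0.96,
                                           seed = i))$response_correct))
  expect_lt(abs(mean(counts) - 489.6), 3)
  # a typical single session lands near the reported retained-trial average
  expect_lt(abs(counts[1] - 488), 4 * sd(counts))
})

test_that("EEG companion mixing controls the shared-source correlation", {
  cfg <- fast_config(trials_per_block = 20L, n_aud = 10L, n_vis = 10L,
                     oddballs = 2L)
  ses <- generate_session(cfg, effect_spec(), seed = 31,
                          keep_windows = FALSE)
  rec <- reconstruct_session(ses)

  # all-zero mixing: zero-lag correlations centred on 0
  comp0 <- generate_eeg_companion(ses, n_channels = 4L, mixing = rep(0, 4),
                                  seed = 41)
  r0 <- sapply(seq_len(ncol(rec$series)), function(tr)
    cor(rec$series[, tr], comp0$channels[, 1, tr]))
  expect_lt(abs(mean(r0)), 0.1)

  # unit mixing with no sensor noise reproduces the latent source exactly
  comp1 <- generate_eeg_companion(ses, n_channels = 2L, mixing = c(1, 0),
                                  noise_sd = 0, seed = 43)
  expect_equal(cor(comp1$channels[, 1, 1], comp1$source[, 1]), 1)

  # uniform mixing 0.3 with known noise follows the attenuation formula
  m <- 0.3; ns <- 0.5
  compm <- generate_eeg_companion(ses, n_channels = 30L,
                                  mixing = rep(m, 30), noise_sd = ns,
                                  seed = 47)
  rm_all <- sapply(seq_len(ncol(rec$series)), function(tr)
    sapply(1:30, function(ch) cor(compm$source[, tr],
                                  compm$channels[, ch, tr])))
  expected_r <- m / sqrt(m^2 + ns^2)
  expect_lt(abs(mean(rm_all) - expected_r), 0.03)

  expect_error(generate_eeg_companion(ses, n_channels = 3L, mixing = c(0, 0)),
               "mixing")
})

test_that("configuration invariants are enforced", {
  expect_error(session_config(n_auditory_cues_per_block = 40L), "equal")
  expect_error(session_config(trials_per_block = 0L), "positive")
  expect_error(session_config(artifact_prefix_len = 4000L),
               "samples_per_window")
  expect_error(effect_spec(base_theta_amplitude = -1), "non-negative")
  expect_error(effect_spec(theta_band = c(8, 5)), "increasing")
  d <- design_summary(session_config())
  expect_equal(d$sampling_rate_hz, 65)
  expect_equal(d$n_trials, 510)
})
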