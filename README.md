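# ciattn

Simulation and analysis of attentional modulation in cochlear-implant (CI)
auditory-nerve recordings.

A cochlear implant in telemetry mode can record electrical activity from
auditory-nerve tissue in short windows: 1.7 ms of acquisition (2048 samples)
followed by a 13.68 ms reset, i.e. 65 windows per second. Averaging each
window (after discarding its artifact-contaminated first 100 samples) turns
the silent 1 s interval between an attention cue and an audiovisual target
into a 65-sample series at an effective rate of

> f_s = 1000 / (1.7 + 13.68) ms ≈ 65 Hz.

`ciattn` provides, for data of this shape, the complete analysis chain —
and, because no raw recordings are distributable, a synthetic-session
generator with the matching statistical structure (6 blocks × 85 trials,
43/42 attend-auditory/attend-visual cues, 8+8 independent oddballs per
block, per-window Gaussian offsets of SD 0.4 mV, 27 ms start jitter, a
decaying artifact prefix, and a theta-band (5–8 Hz) amplitude effect of
configurable gain on attend-auditory trials):

* **Reconstruction** — prefix discard + window averaging; optional 4–25 Hz
  hamming-windowed sinc FIR (order 424) applied one-pass zero-phase.
* **Spectra** — demeaned, detrended, Hann-tapered PSD on the integer-Hz
  bins 4–25; band summaries (theta 5–8, alpha 9–13, beta 14–24 Hz);
  Cousineau–Morey within-subject error bars.
* **Inference** — dependent-samples cluster-based permutation test over
  frequency bins (one-tailed, sign-flip null, add-one Monte-Carlo p, exact
  enumeration option), band-averaged sign-flip tests, paired Cohen's d,
  behavioural statistics.
* **Decoding** — per-trial spectra classified with kNN (odd k from
  1…⌊n/10⌋ by stratified shuffled two-fold CV), label-permutation chance
  levels with `p = (1 + #{perm ≥ obs}) / (1 + n_perm)`, one-sided group t
  tests and a band × type repeated-measures ANOVA with partial η².
* **Volume-conduction check** — zero-lag Pearson correlations against a
  companion multichannel EEG and JZS Bayes factors
  (ln BF₁₀ > 1.1 substantial, > 2.3 strong evidence for shared signal).

The repository is organised as an analysis workflow: numbered drivers in
`analysis/01_simulate.R` … `analysis/06_volume_conduction.R` (configured by
`analysis/config.yaml`) run the stages over the package functions in `R/`
and write their tables under `results/`.

## Worked example

Simulate one subject, reconstruct, test the theta contrast and decode:

```r
library(ciattn)

cfg <- session_config()                      # 6 x 85 design, 65 x 2048 windows
eff <- effect_spec(attend_auditory_gain = 1.3)

ses <- generate_session(cfg, eff, seed = 1, keep_windows = FALSE)
ses <- simulate_behavior(ses, seed = 2)      # ~96% correct
rec <- reconstruct_session(ses, correct_only = TRUE)
sp  <- trial_psd(rec$series, rec$sampling_rate)

bp  <- band_average(sp, "theta")
cue <- rec$meta$cue
c(auditory = mean(bp[cue == "auditory"]), visual = mean(bp[cue == "visual"]))
#>    auditory      visual
#> 0.009634895 0.007867634
```

The attend-auditory theta band power is ~22% higher — the injected gain of
1.3 on the latent theta amplitude, diluted by the offset-noise floor. At
the group level the workflow prints (16 simulated subjects, seed in
`analysis/config.yaml`):

```
full-spectrum cluster test: 1 cluster(s), p = 2e-04, d = 1.44
theta band test: t =  4.64, p = 1e-04, d = 1.16
alpha band test: t =  0.77, p = 0.22, d = 0.19
beta  band test: t =  0.11, p = 0.454, d = 0.03
```

i.e. the cluster test recovers the theta-specific contrast (the add-one
Monte-Carlo floor at 10,000 randomizations is ~1e-4) while the unmodulated
alpha/beta bands stay null. Single-trial decoding on the same cohort:

```
broadband observed > chance: t(15) = 3.83, p = 0.000822, d = 0.96
theta     observed > chance: t(15) = 3.22, p = 0.00284, d = 0.81
subjects with p < 0.05 in any band: 10 of 16
```

with per-subject observed accuracies of 0.52–0.64 against permutation
chance levels within 0.01 of 0.50.

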