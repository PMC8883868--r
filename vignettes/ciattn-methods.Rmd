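---
title: "Simulating and analysing attentional modulation in cochlear-implant auditory-nerve recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing attentional modulation in cochlear-implant auditory-nerve recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciattn)
```

## The scientific setting

A cochlear implant (CI) can be switched into a telemetry mode in which an
intracochlear electrode *records* from auditory-nerve tissue instead of
stimulating it. During the silent interval between an attention cue and an
audiovisual target, such recordings make it possible to ask whether
top-down selective attention modulates activity at the earliest neural
stage of hearing — the spiral ganglion cells whose axons form the auditory
nerve, innervated by the lateral olivocochlear efferent system.

The acquisition scheme is unusual and drives the whole analysis design. The
implant cannot record continuously: it acquires short windows of 1.7 ms
(2048 samples, i.e. ~1.2 MHz inside the window) separated by 13.68 ms reset
periods. One window plus one reset is 15.38 ms, so 65 windows per second
are collected and the 1 s cue–target interval yields, after reducing every
window to a single value, a 65-sample series at an effective rate of 65 Hz.
Each window additionally carries a random DC offset from the acquisition
chain (Gaussian, SD 0.4 mV), a filter artifact over its first 100 samples
(0.083 ms, which are discarded), and the start of the first window jitters
by up to 27 ms.

`ciattn` implements the full analysis chain for such data as a tested R
package — session simulation, series reconstruction, spectral analysis,
cluster-based permutation inference, single-trial decoding, and a Bayesian
volume-conduction check — organised as an analysis workflow (`analysis/01`
… `analysis/06`) over package functions.

## The synthetic-session generator

No raw recordings ship with the package; `generate_session()` produces
sessions with the statistical structure the analysis assumes, so every
stage is testable end to end.

**Design.** A session is 6 blocks of 85 trials: exactly 43 attend-auditory
and 42 attend-visual cues per block, plus 8 visual-oddball and 8
auditory-oddball trials drawn independently within each block (a trial can
be both). Behavioural responses are correct independently with probability
0.96, matching the high accuracy of this simple detection task, so about
488 of 510 trials survive correct-trial selection.

**Latent signal.** Each trial's 1 s latent process is broadband Gaussian
background plus a theta-band (5–8 Hz) component. The theta component is
*amplitude-modulated narrow-band Gaussian noise* — white noise band-limited
to 5–8 Hz and rescaled — rather than a pure sinusoid, because prestimulus
CI spectra are broad and peakless; a sinusoid would concentrate power in a
single bin and make every downstream test unrealistically easy. On
attend-auditory trials the theta amplitude is multiplied by
`attend_auditory_gain`; an optional log-normal per-subject jitter
(`per_subject_gain_sd`) creates subject heterogeneity.

**Defaults.** The acquisition parameters (window/reset durations, 2048
samples, offset SD 0.4 mV, 27 ms jitter, 100-sample prefix) are the study
conditions. The latent-signal amplitudes are not printed anywhere and were
fixed once at values a physiologist would call plausible for this channel:
base theta SD 0.1 mV and broadband SD 0.1 mV, i.e. well below the 0.4 mV
offset-noise floor that dominates the reconstructed series, so
condition effects are a modest fraction of total band power (the default
gain 1.3 yields a ~20–25% theta band-power contrast after reconstruction).

**Numerical fidelity.** The latent process is synthesised at a configurable
rate (`latent_rate`, default 2080 Hz = 32 × 65) and linearly interpolated
to the window sample times, instead of literally generating 1.2 MHz noise.
A 4–25 Hz signal changes negligibly within a 1.7 ms window, so the window
averages — the only thing any later stage sees — are numerically equivalent
while desk-scale runtimes stay in seconds. For the same reason the
aliasing structure of the broadband background (white noise folded into the
0–32.5 Hz band of the 65 Hz series) is independent of `latent_rate`.

**Choices where the design was open.**

* The 27 ms jitter is modelled as uniform on [0, 27] ms per trial
  (maximum-entropy over the stated range; whether the real jitter applied
  per trial or per block is not documented).
* "A random offset added to each of the recordings" is read as one offset
  per *window*, since each window is an independent acquisition.
* The artifact occupying the first 100 samples has no documented shape;
  it is simulated as a deterministic exponential decay of configurable
  amplitude, which is exactly what is needed to *test* that reconstruction
  is artifact-invariant.
* `keep_windows = FALSE` reduces each trial to its 65-sample series at
  generation time using the standard prefix-discard average (a full
  session's raw windows occupy ~0.5 GB); the reduction is
  sample-identical to retaining the windows and averaging later, which is
  asserted by a test.

## Reconstruction

`window_average()` discards the first `discard_n` samples of every window
(default 100) and averages the rest; concatenating the 65 window means
gives the trial series. The operation is linear and, by construction,
invariant to anything written over the discarded prefix.

The optional band-pass is a hamming-windowed sinc FIR, 4–25 Hz, order 424
(425 symmetric taps), applied in one forward pass with exact group-delay
compensation (`apply_zerophase()`). A 425-tap kernel is much longer than a
65-sample trial, so each trial is mirror-extended (reflection about the
edge sample, applied periodically) before filtering and truncated back;
zero padding is available as an alternative. The original toolbox pads
internally in an undocumented way — our padding is an explicit choice, not
a claim about the original. Because all statistics are computed *inside*
the passband on per-bin or per-feature standardized quantities, they are
invariant to the filter's in-band gain, and the workflow therefore runs
its spectral stages on unfiltered series by default (`apply_filter`
toggles this).

## Spectral analysis

`trial_psd()` demeans, least-squares detrends, applies a symmetric Hann
taper and reports one-sided power on the integer-Hz bins 4–25 (22 bins: a
1 s window gives exactly 1 Hz resolution, and no zero-padding interpolation
is used). Power is normalised by taper energy (`2 |X|² / (fs Σw²)`, DC not
doubled); the scale convention is irrelevant to every inference but fixed
and tested against a direct DFT-summation oracle, including Parseval
consistency of the untruncated spectrum.

Bands: broadband 4–25 Hz, theta 5–8, alpha 9–13, beta 14–24; band power is
the arithmetic mean over the band's bins (theta averages bins 5, 6, 7, 8).
The 5-point moving average (`smooth_spectrum()`) exists for display only
and never feeds statistics. Within-subject error bars use the
Cousineau–Morey method: per-subject centring plus the √(C/(C−1)) bias
correction.

## Condition-contrast inference

`cluster_permutation_test()` implements the dependent-samples cluster test
on the 1-D frequency axis: per-bin paired t, one-tailed cluster-forming
threshold at α = 0.05 (the conventional default; configurable), cluster
mass = summed t over contiguous supra-threshold bins, and a null built by
sign-flipping each subject's whole difference vector — the standard
exchangeability scheme for dependent samples, which preserves
within-subject structure. `band_permutation_test()` is the single-bin case
used for pre-averaged theta/alpha/beta power. Monte-Carlo p uses the
add-one convention `(1 + #{null ≥ obs}) / (1 + n_perm)`, so 10,000
randomizations bound p below by ~1e-4; `n_perm = "exhaustive"` enumerates
all 2^n sign patterns for n ≤ 20 and returns the exact p, which the tests
compare against an independent enumeration oracle. Effect sizes are paired
Cohen's d (mean difference / SD of differences). Theta and alpha are
tested separately without cross-band correction — a deliberate choice,
noted rather than hidden.

One behavioural caveat the simulation exposes: with 43 auditory vs 42
visual cues per block, the *expected* correct-count difference between
conditions is ~5.5 trials, and under purely binomial responses the paired
t on counts detects this design asymmetry at n = 16 more often than not.
Real behaviour is lumpier than an independent Bernoulli model (lapses,
fatigue, block effects), which inflates the count variance and can mask
the asymmetry; the simulator makes it visible because its behaviour model
is clean.

## Single-trial decoding

Per subject and band, single-trial spectra become feature vectors
(broadband 22, theta 4, alpha 5, beta 11 columns), standardized to zero
mean and unit variance over *all* of the subject's trials. Full-data
scaling leaks scale information across CV folds; it is retained because it
is the procedure under study, and the cleaner within-fold variant is a
documented alternative. The classifier is kNN with Euclidean distance on
the standardized features; k is chosen from the odd grid 1 … ⌊n/10⌋ (step
2 — odd k avoids two-class vote ties) by stratified, shuffled two-fold CV,
ties going to the smallest k. Distance ties resolve to the lowest training
index, making every prediction deterministic. Note that the grid search
and the final evaluation reuse the same data (again the procedure under
study), which is optimistic in absolute terms but cancels in the
observed-vs-chance contrast.

The chance level is the mean CV accuracy over 1000 global label shuffles
re-run through the same stratified-fold machinery (shuffles are not
re-stratified per fold; the fold assignment is rebuilt from each shuffled
label vector). Group inference: one-sided paired t (observed > chance) per
band with paired d, and a band × type repeated-measures ANOVA (via
`stats::aov` with within-subject error strata) reporting partial
η² = SS_effect / (SS_effect + SS_error); for 16 subjects and 4 bands the
dfs are (3, 45) and (1, 15). Because the simulated effect lives in the
theta band by construction, simulated cohorts typically show a band × type
interaction; recordings whose attentional signature is spread across the
spectrum would not, and emulating that would require modulating additional
bands in the generator.

## Volume-conduction check

If the CI series were volume-conducted cortical activity, simultaneous EEG
should correlate with it at zero lag. `generate_eeg_companion()` builds a
55-channel surrogate EEG whose channel c is independent sensor noise plus
`mixing[c]` times the trial's (z-scored) CI series; `mixing = 0`
reproduces the null of no shared instantaneous source.
`assess_volume_conduction()` computes per-trial zero-lag Pearson
correlations per channel and evaluates the JZS (Jeffreys–Zellner–Siow)
Bayes factor by adaptive numerical integration of the one-dimensional
integral on a log-transformed axis (stable to at least n = 510 and
|r| = 0.999). Evidence thresholds on the ln scale: > 1.1 substantial,
> 2.3 strong evidence *for* volume conduction. Because "the average
Bayesian correlation over trials" is ambiguous, both aggregates are
reported per channel — the mean of per-trial ln BF₁₀ (default verdict
basis) and the ln BF₁₀ of the trial-averaged r. Channel exclusion (e.g.
electrodes above the implant) is a user-supplied list.

## Reproducibility and problem sizes

Every stochastic stage takes its seed from one master seed through
`derive_seed()` (an affine hash modulo 2³¹−1, one stream per subject and
stage), so full runs are bit-identical and adding subjects never perturbs
existing ones.

The test suite exercises the complete pipeline at reduced problem sizes
chosen once: property and calibration suites use 2–4 blocks of 15–40
trials, 8–16 samples per window, a 260–520 Hz latent rate, and permutation
counts of 100–1000; the type-I-error study uses 200 simulated 16-subject
cohorts and the recovery study 10 cohorts at attend gain 1.5 with 100
decoding permutations. Full-scale defaults (6 × 85 trials, 2048-sample
windows, 10,000/1000 permutations) remain the package defaults and drive
the `analysis/` workflow.

## Limitations

The generator emulates the *statistical* structure the analysis assumes —
design counts, windowed acquisition, offset/jitter/artifact nuisances, a
single condition-dependent narrow-band effect — not cochlear physiology:
no electrode geometry, current spread, evoked responses, loudness
psychophysics, or realistic behavioural lapse structure. Passing tests
therefore certify the analysis machinery (calibration, oracle equivalence,
recovery under a known effect), not claims about real auditory-nerve data.
Delta-band activity is out of reach by design: a 1 s window cannot resolve
frequencies below ~1–4 Hz, which is also why the analysis grid starts at
4 Hz.
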