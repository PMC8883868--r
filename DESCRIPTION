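Package: ciattn
Title: Simulation and Analysis of Attentional Modulation in Cochlear-Implant
    Auditory-Nerve Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse windowed auditory-nerve recordings
    taken through a cochlear implant during a silent cue-target interval of a
    crossmodal attention task. Includes a synthetic-session generator that
    reproduces the block design, windowed acquisition scheme (short recording
    windows followed by reset periods), per-window offset noise, start jitter
    and filter-artifact prefixes of such recordings; reconstruction of
    per-trial 65 Hz time series by prefix discard and window averaging;
    Hann-tapered power spectral density estimation on 4-25 Hz with band
    summaries and within-subject error bars; dependent-samples cluster-based
    permutation tests with sign-flip nulls and paired effect sizes; k-nearest
    neighbour decoding of attended modality with stratified two-fold
    cross-validation and permutation chance levels; and a zero-lag Bayesian
    correlation check (Jeffreys-Zellner-Siow prior) against companion EEG
    channels to rule out volume conduction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
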