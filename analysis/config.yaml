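# Run configuration for the analysis workflow (schema: ciattn::validate_config).
# An empty file means full study defaults: 6 blocks x 85 trials, 43/42 cues,
# 8+8 oddballs, 65 x 2048-sample windows, order-424 band-pass, 10000 cluster
# randomizations, 1000 decoding permutations, 16 subjects.
seed: 20260928
n_subjects: 16
# Decoding permutations are reduced from 1000 so the demonstration workflow
# finishes in a few minutes; the package default (run_config()) keeps 1000.
n_perm_decode: 200
effect:
  attend_auditory_gain: 1.3
  per_subject_gain_sd: 0.15
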