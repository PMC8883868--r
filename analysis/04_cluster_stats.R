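#!/usr/bin/env Rscript
# Stage 4: condition-contrast inference.
#
# Cluster-based permutation test over the 4-25 Hz bins (dependent-samples t,
# one-tailed, 10,000 sign-flip randomizations), band-averaged sign-flip
# tests for theta/alpha/beta, paired effect sizes, and the behavioural
# statistics.

suppressPackageStartupMessages(library(ciattn))

cfg <- validate_config("analysis/config.yaml")
out <- "results/stats"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spectra <- utils::read.delim("results/spectra/condition_spectra.tsv")
band_powers <- utils::read.delim("results/spectra/band_powers.tsv")
subjects <- sort(unique(spectra$subject))
freqs <- sort(unique(spectra$freq))
cond_mat <- function(cond) t(sapply(subjects, function(id) {
  d <- spectra[spectra$subject == id & spectra$condition == cond, ]
  d$power[order(d$freq)]
}))

set.seed(derive_seed(cfg$seed, 0))
cluster <- cluster_permutation_test(cond_mat("auditory"),
                                    cond_mat("visual"),
                                    n_perm = cfg$n_perm_cluster,
                                    cluster_alpha = cfg$cluster_alpha,
                                    freqs = freqs)
cat("full-spectrum cluster test: ", length(cluster$clusters),
    " cluster(s), p = ", signif(cluster$p_value, 4), ", d = ",
    round(cluster$effect_size_d, 2), "\n", sep = "")

bands <- setdiff(unique(band_powers$band), "broadband")
band_tests <- lapply(bands, function(b) {
  bp <- band_powers[band_powers$band == b, ]
  bt <- band_permutation_test(bp$auditory, bp$visual,
                              n_perm = cfg$n_perm_cluster)
  cat(sprintf("%-5s band test: t = %5.2f, p = %s, d = %.2f\n", b,
              bt$t_observed, signif(bt$p_value, 3), bt$effect_size_d))
  list(band = b, t = bt$t_observed, p = bt$p_value, d = bt$effect_size_d)
})

# behavioural statistics from the stage-1 metadata
counts <- t(sapply(seq_along(subjects), function(s) {
  md <- utils::read.delim(sprintf("results/sessions/%s_trials.tsv",
                                  subjects[s]))
  c(auditory = sum(md$cue == "auditory" & md$response_correct),
    visual = sum(md$cue == "visual" & md$response_correct),
    n_aud = sum(md$cue == "auditory"), n_vis = sum(md$cue == "visual"))
}))
theta_bp <- band_powers[band_powers$band == "theta", ]
beh <- behavior_stats(as.data.frame(counts[, c("auditory", "visual")]),
                      cbind(theta_bp$auditory, theta_bp$visual),
                      cbind(counts[, "auditory"] / counts[, "n_aud"],
                            counts[, "visual"] / counts[, "n_vis"]))
cat(sprintf("correct trials auditory vs visual: t(%d) = %.2f, p = %.3f, d = %.2f\n",
            beh$df, beh$paired_t, beh$p, beh$d))
cat(sprintf("theta power vs performance: auditory r = %.3f (p = %.3f), visual r = %.3f (p = %.3f)\n",
            beh$power_performance$auditory$r, beh$power_performance$auditory$p,
            beh$power_performance$visual$r, beh$power_performance$visual$p))

utils::write.table(data.frame(freq = freqs, t = cluster$t_observed),
                   file.path(out, "per_bin_t.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(
  cluster = list(p = cluster$p_value, d = cluster$effect_size_d,
                 n_permutations = cluster$n_permutations,
                 masses = cluster$cluster_masses,
                 spans = cluster$cluster_spans),
  band_tests = band_tests,
  behavior = list(t = beh$paired_t, df = beh$df, p = beh$p, d = beh$d,
                  power_performance = beh$power_performance)),
  file.path(out, "stats.json"), auto_unbox = TRUE, digits = NA)
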