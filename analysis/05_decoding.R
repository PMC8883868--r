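#!/usr/bin/env Rscript
# Stage 5: single-trial decoding of the attended modality.
#
# Per subject and band: standardized single-trial power spectra, kNN with
# the grid-searched neighbour count, stratified shuffled twofold CV, and a
# label-permutation chance level; then the group statistics (one-sided
# paired t per band, band x type repeated-measures ANOVA).

suppressPackageStartupMessages(library(ciattn))

cfg <- validate_config("analysis/config.yaml")
out <- "results/decoding"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

acc_rows <- list(); p_rows <- list()
for (s in seq_len(cfg$n_subjects)) {
  id <- sprintf("S%02d", s)
  series <- read_series_tsv(sprintf("results/reconstructed/%s_series.tsv",
                                    id))
  sp <- trial_psd(series$series, series$sampling_rate)
  dec <- decode_subject(sp, series$meta$cue, cfg$fois,
                        n_permutations = cfg$n_perm_decode,
                        seed = derive_seed(cfg$seed, s * 10 + 3))
  for (b in names(dec)) {
    acc_rows[[length(acc_rows) + 1L]] <- data.frame(
      subject = id, foi = b, type = c("observed", "chance"),
      accuracy = c(dec[[b]]$observed_accuracy, dec[[b]]$chance_level),
      best_k = dec[[b]]$best_k)
    p_rows[[length(p_rows) + 1L]] <- data.frame(subject = id, foi = b,
                                                p = dec[[b]]$p_value)
  }
  cat(id, ": broadband observed ",
      round(dec$broadband$observed_accuracy, 3), " vs chance ",
      round(dec$broadband$chance_level, 3), " (p = ",
      signif(dec$broadband$p_value, 3), ", k = ", dec$broadband$best_k,
      ")\n", sep = "")
}
acc <- do.call(rbind, acc_rows)
subject_p <- do.call(rbind, p_rows)
utils::write.table(acc, file.path(out, "accuracy.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(subject_p, file.path(out, "subject_p.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

gs <- group_decoding_stats(acc[, c("subject", "foi", "type", "accuracy")],
                           subject_p)
for (b in names(gs$per_foi))
  cat(sprintf("%-9s observed > chance: t(%d) = %.2f, p = %s, d = %.2f\n",
              b, gs$per_foi[[b]]$df, gs$per_foi[[b]]$t,
              signif(gs$per_foi[[b]]$p, 3), gs$per_foi[[b]]$d))
print(gs$anova, row.names = FALSE)
cat("subjects with p < 0.05 in any band:", gs$n_subjects_above_chance,
    "of", cfg$n_subjects, "\n")
jsonlite::write_json(list(per_foi = gs$per_foi, anova = gs$anova,
                          n_subjects_above_chance =
                            gs$n_subjects_above_chance),
                     file.path(out, "group_stats.json"),
                     auto_unbox = TRUE, digits = NA, dataframe = "rows")
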