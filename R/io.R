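#' Write / read session containers
#'
#' The on-disk session layout (version 1) is a plain-text pair: a trial
#' metadata TSV (one row per trial: subject, block, in-block and global
#' trial index, cue, oddball flags, response correctness, start jitter) and,
#' for reconstructed data, a series TSV with one row per trial
#' (`trial_index`, `cue`, `s1` ... `s65`) plus a JSON sidecar recording the
#' sampling rate, filter settings and preprocessing provenance.
#'
#' @param session A `ci_session`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_session_metadata <- function(session, path) {
  utils::write.table(session_metadata(session), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_metadata
#' @param series_set A `ci_series_set` from [reconstruct_session()].
#' @param sidecar Path of the JSON provenance sidecar (default: `path` with
#'   `.json` appended).
#' @export
write_series_tsv <- function(series_set, path,
                             sidecar = paste0(path, ".json")) {
  stopifnot(inherits(series_set, "ci_series_set"))
  n <- nrow(series_set$series)
  df <- cbind(series_set$meta[, c("subject_id", "trial_index", "cue")],
              as.data.frame(t(series_set$series)))
  names(df)[-(1:3)] <- paste0("s", seq_len(n))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(layout_version = 1,
                            sampling_rate = series_set$sampling_rate,
                            filtered = series_set$filtered,
                            n_samples = n, n_trials = ncol(series_set$series)),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session_metadata
#' @export
read_series_tsv <- function(path, sidecar = paste0(path, ".json")) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta_cols <- c("subject_id", "trial_index", "cue")
  prov <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
  else list(sampling_rate = 65, filtered = FALSE)
  series <- t(as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE]))
  dimnames(series) <- NULL
  structure(list(series = series, meta = df[, meta_cols, drop = FALSE],
                 sampling_rate = prov$sampling_rate,
                 filtered = isTRUE(prov$filtered),
                 subject_id = df$subject_id[1]),
            class = "ci_series_set")
}
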