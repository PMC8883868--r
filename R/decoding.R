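#' Feature matrix for single-trial decoding
#'
#' Extracts the band's integer-Hz power bins as feature columns (broadband
#' 22, theta 4, alpha 5, beta 11 columns) and aligns the cue labels.
#'
#' @param spectra Trial spectra (`freqs` plus bins-by-trials `power`) from
#'   [trial_psd()] on a series matrix.
#' @param labels Per-trial cue labels.
#' @param foi A [foi_band()] or band name.
#' @return List with `x` (trials x bins matrix) and `y` (factor of labels).
#' @export
build_features <- function(spectra, labels, foi = foi_band("broadband")) {
  if (is.character(foi)) foi <- foi_band(foi)
  idx <- which(spectra$freqs >= foi$range[1] - 1e-9 &
                 spectra$freqs <= foi$range[2] + 1e-9)
  if (length(idx) < diff(foi$range) + 1)
    stop("build_features: spectrum is missing bins of band ", foi$name,
         call. = FALSE)
  x <- t(spectra$power[idx, , drop = FALSE])
  colnames(x) <- paste0("f", spectra$freqs[idx])
  if (nrow(x) != length(labels))
    stop("build_features: one label per trial required", call. = FALSE)
  list(x = x, y = factor(as.character(labels)))
}

#' Standardize features to zero mean and unit variance
#'
#' Column-wise z-scoring over all of a subject's trials (full-data scaling;
#' see Details). The SD convention is configurable.
#'
#' @param x Trials x features matrix.
#' @param sd_type `"sample"` (`n - 1` denominator, default) or
#'   `"population"` (`n`).
#' @details Scaling on the full data before cross-validation leaks the
#'   feature scale across folds; it is retained as the default because it is
#'   the procedure under study. Use [grid_search_k()]'s `scale_within_fold`
#'   for the cleaner variant.
#' @return The standardized matrix.
#' @export
standardize_features <- function(x, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  x <- as.matrix(x)
  n <- nrow(x)
  mu <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  if (any(s == 0))
    stop("standardize_features: zero-variance feature column", call. = FALSE)
  sweep(sweep(x, 2, mu), 2, s, "/")
}

#' Candidate neighbour counts for the k grid
#'
#' Odd integers from 1 to 10% of the trial count (`floor(n/10)`), step 2 —
#' odd k avoids two-class vote ties.
#'
#' @param n_trials Number of trials.
#' @return Integer vector of candidate k (just `1` when `n_trials < 10`).
#' @export
make_k_grid <- function(n_trials) {
  top <- floor(n_trials / 10)
  if (top < 1) return(1L)
  seq.int(1L, as.integer(top), by = 2L)
}

#' k-nearest-neighbour prediction
#'
#' Majority vote among the `k` Euclidean-nearest training points. Odd `k`
#' precludes two-class ties; distance ties are broken by the lowest training
#' index, making predictions fully deterministic.
#'
#' @param train_x,train_y Training features (rows = points) and labels.
#' @param test_x Test features.
#' @param k Odd neighbour count, `k <= nrow(train_x)`.
#' @return Factor of predicted labels.
#' @export
knn_predict <- function(train_x, train_y, test_x, k = 1L) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  k <- as.integer(k)
  if (k %% 2L != 1L) stop("knn_predict: k must be odd", call. = FALSE)
  if (k > nrow(train_x)) stop("knn_predict: k exceeds training size",
                              call. = FALSE)
  train_y <- factor(train_y)
  d2 <- sq_dist(test_x, train_x)  # test x train
  pred <- apply(d2, 1, function(dr) {
    nb <- order(dr)[seq_len(k)]   # order() breaks ties by lowest index
    votes <- table(train_y[nb])
    names(votes)[which.max(votes)]
  })
  factor(pred, levels = levels(train_y))
}

# Squared Euclidean distances between row sets (a: m x p, b: n x p).
sq_dist <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Stratified fold assignment: within each class, shuffled trials are dealt
# round-robin into n_folds folds. Returns integer fold ids per trial.
stratified_folds <- function(y, n_folds = 2L) {
  y <- factor(y)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    if (length(idx) < n_folds)
      stop("stratified_folds: class '", cl, "' has fewer members than folds",
           call. = FALSE)
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# CV accuracy at one k using a precomputed neighbour-order matrix.
# ord: n x n matrix; ord[, i] lists all points by increasing distance from
# point i (self first). fold: fold ids; y: labels (factor).
cv_accuracy_from_order <- function(ord, fold, y, k, n_folds = 2L) {
  n <- length(y)
  correct <- 0L
  y_int <- as.integer(y)
  for (f in seq_len(n_folds)) {
    in_train <- fold != f
    test_idx <- which(!in_train)
    for (i in test_idx) {
      o <- ord[, i]
      nb <- o[in_train[o]][seq_len(k)]
      vote <- sum(y_int[nb] == 1L)
      pred <- if (vote * 2L > k) 1L else 2L
      correct <- correct + (pred == y_int[i])
    }
  }
  correct / n
}

neighbour_order <- function(x) {
  d2 <- sq_dist(x, x)
  apply(d2, 2, order)  # column i: points sorted by distance to i
}

#' Grid search for the best neighbour count
#'
#' For each candidate k, mean accuracy over a stratified, shuffled
#' `n_folds`-fold cross-validation; ties go to the smallest k. The same fold
#' assignment is used for every candidate.
#'
#' @param x Trials x features matrix (already standardized).
#' @param y Two-level label factor.
#' @param grid Candidate k values (defaults to [make_k_grid()]).
#' @param n_folds Number of CV folds.
#' @param seed Optional integer seed driving the fold shuffle.
#' @return List with `best_k`, `scores` (named accuracy per k), `fold`.
#' @export
grid_search_k <- function(x, y, grid = make_k_grid(nrow(x)), n_folds = 2L,
                          seed = NULL) {
  x <- as.matrix(x); y <- factor(y)
  if (nlevels(y) != 2L) stop("grid_search_k: need exactly 2 classes",
                             call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  fold <- stratified_folds(y, n_folds)
  grid <- as.integer(grid)
  min_train <- min(table(fold))
  grid <- grid[grid <= length(y) - max(table(fold))]
  if (!length(grid)) grid <- 1L
  ord <- neighbour_order(x)
  scores <- vapply(grid, function(k)
    cv_accuracy_from_order(ord, fold, y, k, n_folds), numeric(1))
  names(scores) <- grid
  best_k <- grid[which.max(scores)]  # which.max takes the first (smallest k)
  list(best_k = best_k, scores = scores, fold = fold)
}

#' Permutation-null decoding of one subject
#'
#' Observed accuracy is the stratified two-fold CV accuracy at `best_k`; the
#' chance level is the mean accuracy over `n_permutations` global label
#' shuffles, each re-run through the same stratified shuffled CV machinery;
#' `p = (1 + #(perm >= observed)) / (1 + n_permutations)`.
#'
#' @param x Trials x features matrix (standardized).
#' @param y Two-level label factor.
#' @param best_k Neighbour count fixed before the permutations (from
#'   [grid_search_k()]).
#' @param n_permutations Label shuffles (1000 in the full procedure).
#' @param n_folds CV folds.
#' @param seed Optional integer seed (folds and shuffles).
#' @return A `ci_decoding_result`: list with `best_k`, `observed_accuracy`,
#'   `permutation_scores`, `chance_level`, `p_value`, `n_trials`.
#' @export
permutation_decode <- function(x, y, best_k, n_permutations = 1000L,
                               n_folds = 2L, seed = NULL) {
  x <- as.matrix(x); y <- factor(y)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (best_k %% 2L != 1L) stop("permutation_decode: best_k must be odd",
                               call. = FALSE)
  ord <- neighbour_order(x)
  fold <- stratified_folds(y, n_folds)
  observed <- cv_accuracy_from_order(ord, fold, y, best_k, n_folds)
  perm <- vapply(seq_len(n_permutations), function(p) {
    yp <- y[sample.int(length(y))]
    fp <- stratified_folds(yp, n_folds)
    cv_accuracy_from_order(ord, fp, yp, best_k, n_folds)
  }, numeric(1))
  structure(list(best_k = as.integer(best_k), observed_accuracy = observed,
                 permutation_scores = perm, chance_level = mean(perm),
                 p_value = (1 + sum(perm >= observed)) / (1 + n_permutations),
                 n_trials = length(y), n_folds = n_folds),
            class = "ci_decoding_result")
}

#' Decode one subject across all bands
#'
#' Convenience wrapper: builds band features from trial spectra,
#' standardizes, grid-searches k, and runs the permutation-null decoding.
#'
#' @param spectra Trial spectra (bins x trials `power` with `freqs`).
#' @param labels Per-trial cue labels.
#' @param fois Band names to decode.
#' @param n_permutations Label shuffles per band.
#' @param seed Optional integer seed.
#' @return Named list of `ci_decoding_result`, one per band.
#' @export
decode_subject <- function(spectra, labels, fois = foi_names(),
                           n_permutations = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- lapply(fois, function(b) {
    ft <- build_features(spectra, labels, foi_band(b))
    xs <- standardize_features(ft$x)
    gs <- grid_search_k(xs, ft$y)
    permutation_decode(xs, ft$y, gs$best_k, n_permutations)
  })
  names(out) <- fois
  out
}

#' Group-level decoding statistics
#'
#' Per-band one-sided paired t (observed > chance) with paired Cohen's d,
#' the two-factor repeated-measures ANOVA (band x type) with partial eta
#' squared per effect, and the count of subjects with per-subject permutation
#' `p < 0.05` in any band.
#'
#' @param accuracy Data frame with columns `subject`, `foi`, `type`
#'   (`"observed"`/`"chance"`), `accuracy`.
#' @param subject_p Optional data frame with columns `subject`, `foi`, `p`
#'   (per-subject permutation p values).
#' @return A `ci_group_decoding`: list with `per_foi` (t, df, p one-sided,
#'   d), `anova` (data frame: effect, df1, df2, F, p, partial eta squared),
#'   `n_subjects_above_chance`.
#' @export
group_decoding_stats <- function(accuracy, subject_p = NULL) {
  accuracy$foi <- factor(accuracy$foi)
  accuracy$type <- factor(accuracy$type, levels = c("observed", "chance"))
  accuracy$subject <- factor(accuracy$subject)
  n_s <- nlevels(accuracy$subject)
  expected <- n_s * nlevels(accuracy$foi) * 2L
  if (nrow(accuracy) != expected || anyNA(accuracy$accuracy))
    stop("group_decoding_stats: need a complete subjects x FOI x type table",
         call. = FALSE)

  per_foi <- lapply(levels(accuracy$foi), function(b) {
    obs <- accuracy$accuracy[accuracy$foi == b & accuracy$type == "observed"]
    cha <- accuracy$accuracy[accuracy$foi == b & accuracy$type == "chance"]
    obs <- obs[order(accuracy$subject[accuracy$foi == b &
                                        accuracy$type == "observed"])]
    cha <- cha[order(accuracy$subject[accuracy$foi == b &
                                        accuracy$type == "chance"])]
    if (stats::sd(obs - cha) == 0 && all(obs == cha)) {
      # degenerate observed == chance case: t is 0 by convention
      return(list(foi = b, t = 0, df = length(obs) - 1L, p = 0.5, d = 0))
    }
    tt <- stats::t.test(obs, cha, paired = TRUE, alternative = "greater")
    list(foi = b, t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value,
         d = tryCatch(cohens_d_paired(obs, cha), error = function(e) NA_real_))
  })
  names(per_foi) <- levels(accuracy$foi)

  fit <- stats::aov(accuracy ~ foi * type +
                      Error(subject / (foi * type)), data = accuracy)
  anova_tab <- rm_anova_table(fit)

  n_above <- NA_integer_
  if (!is.null(subject_p))
    n_above <- length(unique(subject_p$subject[subject_p$p < 0.05]))

  structure(list(per_foi = per_foi, anova = anova_tab,
                 n_subjects_above_chance = n_above),
            class = "ci_group_decoding")
}

# Extract F, df and partial eta squared from an aov multistratum fit.
rm_anova_table <- function(fit) {
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    res_i <- which(terms == "Residuals")
    if (!length(res_i)) next
    ss_err <- tab[res_i, "Sum Sq"]; df_err <- tab[res_i, "Df"]
    for (i in seq_len(nrow(tab))) {
      if (i == res_i || is.na(tab[i, "F value"])) next
      ss <- tab[i, "Sum Sq"]
      rows[[length(rows) + 1L]] <- data.frame(
        effect = terms[i], df1 = tab[i, "Df"], df2 = df_err,
        F = tab[i, "F value"], p = tab[i, "Pr(>F)"],
        pes = ss / (ss + ss_err))
    }
  }
  do.call(rbind, rows)
}

#' @export
print.ci_decoding_result <- function(x, ...) {
  cat("<ci_decoding_result> k = ", x$best_k, ", observed = ",
      round(x$observed_accuracy, 3), ", chance = ",
      round(x$chance_level, 3), ", p = ", signif(x$p_value, 3), " (",
      length(x$permutation_scores), " permutations, ", x$n_trials,
      " trials)\n", sep = "")
  invisible(x)
}
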