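#' Per-bin dependent-samples t statistics
#'
#' Paired t per frequency bin: `t = mean(d) / (sd(d) / sqrt(n))` with the
#' `n - 1` SD denominator, `d` the per-subject condition difference.
#'
#' @param cond_a,cond_b Numeric matrices, subjects x bins, rows matched by
#'   subject.
#' @return Numeric vector of t values (one per bin); bins with zero
#'   difference variance are `NaN` with a warning.
#' @export
dependent_t <- function(cond_a, cond_b) {
  cond_a <- as.matrix(cond_a); cond_b <- as.matrix(cond_b)
  if (!all(dim(cond_a) == dim(cond_b)))
    stop("dependent_t: condition matrices must have matching dimensions",
         call. = FALSE)
  n <- nrow(cond_a)
  if (n < 2L) stop("dependent_t: need at least 2 subjects", call. = FALSE)
  d <- cond_a - cond_b
  m <- colMeans(d)
  s <- apply(d, 2, stats::sd)
  if (any(s == 0 & m != 0))
    warning("dependent_t: zero difference variance with nonzero mean; ",
            "t undefined for those bins")
  ifelse(s == 0 & m == 0, 0, m / (s / sqrt(n)))
}

# t statistics for many sign-flip permutations at once.
# d: subjects x bins difference matrix; signs: subjects x n_perm of +-1.
# Returns bins x n_perm matrix of t values.
signflip_t <- function(d, signs) {
  n <- nrow(d)
  sum_d <- crossprod(d, signs)                    # bins x n_perm
  sum_d2 <- colSums(d^2)                          # invariant under sign flips
  m <- sum_d / n
  v <- (sum_d2 - n * m^2) / (n - 1)
  v[v < 0] <- 0
  t_mat <- m / sqrt(v / n)
  t_mat[v == 0] <- 0
  t_mat
}

# Contiguous supra-threshold clusters on a 1-D ordered axis.
# Returns list of integer index vectors.
find_clusters <- function(stat, threshold) {
  supra <- stat > threshold
  if (!any(supra)) return(list())
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mapply(function(s, e) seq.int(s, e), starts[r$values], ends[r$values],
         SIMPLIFY = FALSE)
}

# Maximum cluster mass per permutation column of a bins x n_perm t matrix.
max_cluster_mass <- function(t_mat, threshold) {
  apply(t_mat, 2, function(tv) {
    cl <- find_clusters(tv, threshold)
    if (!length(cl)) 0 else max(vapply(cl, function(ix) sum(tv[ix]),
                                       numeric(1)))
  })
}

#' Cluster-based permutation test over frequency bins
#'
#' Dependent-samples cluster test on a 1-D ordered frequency axis: per-bin
#' paired t values are thresholded at the one-tailed critical t for
#' `cluster_alpha`, contiguous supra-threshold bins are merged into clusters
#' whose mass is the summed t, and the null distribution of the maximum
#' cluster mass is built by randomly flipping the sign of each subject's
#' whole difference vector (preserving within-subject structure). The
#' Monte-Carlo p uses the add-one convention
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`, so the smallest reachable
#' p at 10,000 randomizations is about 1e-4.
#'
#' @param cond_a,cond_b Subjects x bins matrices (rows matched); the test is
#'   one-tailed for `cond_a > cond_b`.
#' @param n_perm Number of random sign-flip permutations, or `"exhaustive"`
#'   to enumerate all `2^n` sign patterns (exact p, no add-one; `n <= 20`).
#' @param cluster_alpha One-tailed per-bin cluster-forming alpha.
#' @param freqs Optional bin frequencies (Hz) used to report cluster spans.
#' @param seed Optional integer seed for the permutation draw.
#' @return A `ci_cluster_test`: list with `band` span per cluster,
#'   `cluster_masses`, `clusters` (bin indices), `max_mass`,
#'   `null_distribution`, `p_value`, `effect_size_d` (paired d of the
#'   bin-averaged contrast), `tail`, `n_permutations`, `exact`.
#' @export
cluster_permutation_test <- function(cond_a, cond_b, n_perm = 10000L,
                                     cluster_alpha = 0.05, freqs = NULL,
                                     seed = NULL) {
  cond_a <- as.matrix(cond_a); cond_b <- as.matrix(cond_b)
  d <- cond_a - cond_b
  n <- nrow(d)
  if (n < 2L) stop("cluster_permutation_test: need >= 2 subjects",
                   call. = FALSE)
  exact <- identical(n_perm, "exhaustive")
  if (!exact && (!is.numeric(n_perm) || n_perm < 1))
    stop("cluster_permutation_test: n_perm must be >= 1 or \"exhaustive\"",
         call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  threshold <- stats::qt(1 - cluster_alpha, df = n - 1)
  t_obs <- dependent_t(cond_a, cond_b)
  clusters <- find_clusters(t_obs, threshold)
  masses <- vapply(clusters, function(ix) sum(t_obs[ix]), numeric(1))
  obs_max <- if (length(masses)) max(masses) else 0

  if (exact) {
    if (n > 20L) stop("exhaustive enumeration limited to n <= 20 subjects",
                      call. = FALSE)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    signs <- t(signs)  # subjects x 2^n
  } else {
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n)
  }
  null_max <- max_cluster_mass(signflip_t(d, signs), threshold)

  p <- if (!length(clusters)) 1 else if (exact)
    mean(null_max >= obs_max - 1e-12)
  else
    (1 + sum(null_max >= obs_max)) / (1 + ncol(signs))

  band_mean_a <- rowMeans(cond_a)
  band_mean_b <- rowMeans(cond_b)
  d_eff <- tryCatch(cohens_d_paired(band_mean_a, band_mean_b),
                    error = function(e) NA_real_)

  structure(list(clusters = clusters, cluster_masses = masses,
                 max_mass = obs_max, t_observed = t_obs,
                 cluster_spans = if (!is.null(freqs))
                   lapply(clusters, function(ix) range(freqs[ix])) else NULL,
                 null_distribution = null_max, p_value = p,
                 effect_size_d = d_eff, tail = "greater",
                 n_permutations = ncol(signs), exact = exact,
                 threshold = threshold),
            class = "ci_cluster_test")
}

#' Sign-flip permutation test on a band-averaged contrast
#'
#' Degenerate single-bin case of the cluster test for pre-averaged band
#' powers: the statistic is the paired t of the per-subject difference, the
#' null flips each subject's difference sign, one-tailed for `a > b`.
#'
#' @param band_values_a,band_values_b Per-subject band powers (matched).
#' @param n_perm Permutation count or `"exhaustive"`.
#' @param seed Optional integer seed.
#' @return A `ci_cluster_test` with a single "cluster" (the band itself).
#' @export
band_permutation_test <- function(band_values_a, band_values_b,
                                  n_perm = 10000L, seed = NULL) {
  a <- matrix(as.numeric(band_values_a), ncol = 1)
  b <- matrix(as.numeric(band_values_b), ncol = 1)
  d <- a - b
  n <- nrow(d)
  if (n < 2L) stop("band_permutation_test: need >= 2 subjects", call. = FALSE)
  exact <- identical(n_perm, "exhaustive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  t_obs <- dependent_t(a, b)
  if (exact) {
    if (n > 20L) stop("exhaustive enumeration limited to n <= 20 subjects",
                      call. = FALSE)
    signs <- t(as.matrix(expand.grid(rep(list(c(-1, 1)), n))))
  } else {
    if (!is.numeric(n_perm) || n_perm < 1)
      stop("band_permutation_test: n_perm must be >= 1", call. = FALSE)
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n)
  }
  null_t <- as.numeric(signflip_t(d, signs))
  p <- if (exact) mean(null_t >= t_obs - 1e-12) else
    (1 + sum(null_t >= t_obs)) / (1 + length(null_t))
  d_eff <- tryCatch(cohens_d_paired(as.numeric(a), as.numeric(b)),
                    error = function(e) NA_real_)
  structure(list(clusters = list(1L), cluster_masses = t_obs,
                 max_mass = t_obs, t_observed = t_obs,
                 null_distribution = null_t, p_value = p,
                 effect_size_d = d_eff, tail = "greater",
                 n_permutations = ncol(signs), exact = exact),
            class = "ci_cluster_test")
}

#' Paired Cohen's d
#'
#' `d = mean(a - b) / sd(a - b)` with the `n - 1` SD denominator.
#'
#' @param a,b Matched per-subject values.
#' @return Scalar effect size.
#' @export
cohens_d_paired <- function(a, b) {
  d <- as.numeric(a) - as.numeric(b)
  if (length(d) < 2L) stop("cohens_d_paired: need >= 2 pairs", call. = FALSE)
  s <- stats::sd(d)
  if (s == 0) {
    if (all(d == 0)) return(0)  # a == b: no effect by convention
    stop("cohens_d_paired: zero SD of differences", call. = FALSE)
  }
  mean(d) / s
}

#' Behavioural statistics
#'
#' Paired t test on per-subject correct-trial counts (attend-auditory vs
#' attend-visual cue), and the per-condition Pearson correlation between
#' subject theta band power and proportion correct.
#'
#' @param correct_counts Data frame/matrix with columns `auditory` and
#'   `visual`: per-subject correct-trial counts per cue condition.
#' @param band_powers Subjects x 2 matrix of theta band power, columns
#'   `auditory` and `visual`.
#' @param prop_correct Subjects x 2 matrix of proportion correct per
#'   condition (same column order).
#' @return A `ci_behavior_stats`: list with `paired_t`, `df`, `p`, `d`, and
#'   `power_performance` (per-condition `r` and `p`).
#' @export
behavior_stats <- function(correct_counts, band_powers, prop_correct) {
  cc <- as.data.frame(correct_counts)
  n <- nrow(cc)
  if (n < 3L) stop("behavior_stats: need >= 3 subjects", call. = FALSE)
  diff <- cc$auditory - cc$visual
  if (stats::sd(diff) == 0) {
    if (any(diff != 0))
      stop("behavior_stats: constant nonzero count difference, t undefined",
           call. = FALSE)
    tt <- list(statistic = 0, parameter = n - 1L, p.value = 1)
    d <- 0
  } else {
    tt <- stats::t.test(cc$auditory, cc$visual, paired = TRUE)
    d <- cohens_d_paired(cc$auditory, cc$visual)
  }
  bp <- as.matrix(band_powers); pc <- as.matrix(prop_correct)
  corr <- lapply(c(auditory = 1, visual = 2), function(j) {
    if (stats::sd(bp[, j]) == 0 || stats::sd(pc[, j]) == 0)
      stop("behavior_stats: degenerate variance in power-performance ",
           "correlation input", call. = FALSE)
    ct <- stats::cor.test(bp[, j], pc[, j])
    list(r = unname(ct$estimate), p = ct$p.value)
  })
  structure(list(paired_t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, d = d, power_performance = corr),
            class = "ci_behavior_stats")
}

#' @export
print.ci_cluster_test <- function(x, ...) {
  cat("<ci_cluster_test> ", length(x$clusters), " cluster(s), max mass ",
      signif(x$max_mass, 4), ", p = ", signif(x$p_value, 4), " (",
      if (x$exact) "exact enumeration" else paste0(x$n_permutations,
                                                   " permutations"),
      ", one-tailed), paired d = ", signif(x$effect_size_d, 3), "\n",
      sep = "")
  invisible(x)
}
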