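test_that("per-bin dependent t matches the textbook formula", {
  set.seed(21)
  a <- matrix(rnorm(16 * 22), 16)
  b <- matrix(rnorm(16 * 22), 16)
  mine <- dependent_t(a, b)
  ref <- sapply(1:22, function(j) {
    d <- a[, j] - b[, j]
    mean(d) / (sd(d) / sqrt(16))
  })
  expect_equal(mine, ref, tolerance = 1e-12)
  expect_equal(dependent_t(a, a), rep(0, 22))
  # constant nonzero difference: undefined statistic is flagged
  expect_warning(tc <- dependent_t(matrix(2, 16, 3), matrix(1, 16, 3)),
                 "zero difference variance")
  expect_true(all(!is.finite(tc)))
  expect_error(dependent_t(a[1, , drop = FALSE], b[1, , drop = FALSE]),
               "2 subjects")
})

test_that("identical conditions give no cluster and p = 1", {
  set.seed(4)
  a <- matrix(rnorm(16 * 22), 16)
  res <- cluster_permutation_test(a, a, n_perm = 200, seed = 1)
  expect_length(res$clusters, 0)
  expect_equal(res$p_value, 1)
})

test_that("an overwhelming shift on bins 5-8 Hz forms a single significant cluster", {
  set.seed(11)
  b <- matrix(rnorm(16 * 22), 16)
  a <- matrix(rnorm(16 * 22), 16)
  shift_bins <- which(4:25 %in% 5:8)
  a[, shift_bins] <- a[, shift_bins] + 5
  res <- cluster_permutation_test(a, b, n_perm = 10000, freqs = 4:25,
                                  seed = 2)
  main <- res$clusters[[which.max(res$cluster_masses)]]
  expect_true(all(shift_bins %in% main))
  span <- res$cluster_spans[[which.max(res$cluster_masses)]]
  # the shifted 5-8 Hz range is covered; a supra-threshold neighbouring
  # null bin may legitimately join the cluster
  expect_lte(span[1], 5); expect_gte(span[1], 4)
  expect_gte(span[2], 8); expect_lte(span[2], 9)
  expect_lte(res$p_value, 0.001)
  expect_gte(res$p_value, 1 / 10001)
})

test_that("exhaustive sign-flip p equals full 2^n enumeration", {
  set.seed(33)
  for (rep_i in 1:3) {
    d <- rnorm(10, mean = 0.4)
    a <- matrix(d, ncol = 1); b <- matrix(0, 10, 1)
    exact <- cluster_permutation_test(a, b, n_perm = "exhaustive",
                                      cluster_alpha = 0.5)
    # single bin with a liberal threshold: the cluster statistic is the t
    band <- band_permutation_test(d, rep(0, 10), n_perm = "exhaustive")
    ref <- oracle_signflip_p(d)
    expect_equal(band$p_value, ref, tolerance = 1e-12)
  }
  # all-positive differences, n = 16: exact one-tailed p = 1 / 2^16
  bandpos <- band_permutation_test(1:16, rep(0, 16), n_perm = "exhaustive")
  expect_equal(bandpos$p_value, 1 / 2^16)
})

test_that("sampled sign-flip p converges to the exact enumeration p", {
  set.seed(8)
  d <- rnorm(9, mean = 0.5)
  exact <- band_permutation_test(d, rep(0, 9), n_perm = "exhaustive")$p_value
  sampled <- band_permutation_test(d, rep(0, 9), n_perm = 20000,
                                   seed = 5)$p_value
  expect_lt(abs(sampled - exact), 0.02)
  expect_equal(band_permutation_test(d, d, n_perm = 100, seed = 1)$p_value, 1)
})

test_that("label exchange negates the statistic and flips the tail", {
  set.seed(14)
  a <- rnorm(12, 1); b <- rnorm(12)
  fwd <- band_permutation_test(a, b, n_perm = "exhaustive")
  rev <- band_permutation_test(b, a, n_perm = "exhaustive")
  expect_equal(rev$t_observed, -fwd$t_observed)
  expect_lt(fwd$p_value, 0.05)
  expect_gt(rev$p_value, 0.95)
})

test_that("p is non-increasing in the injected effect on a fixed noise draw", {
  set.seed(19)
  noise <- rnorm(12)
  ps <- sapply(c(0, 0.3, 0.8, 1.5), function(shift)
    band_permutation_test(noise + shift, rep(0, 12),
                          n_perm = "exhaustive")$p_value)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("the sampled band test rejects a true null at about the nominal rate", {
  set.seed(90)
  rej <- sapply(1:400, function(i) {
    d <- rnorm(12)
    band_permutation_test(d, rep(0, 12), n_perm = 300)$p_value < 0.05
  })
  # 95% binomial envelope around 0.05 at 400 repetitions
  expect_gt(mean(rej), 0.05 - 1.96 * sqrt(0.05 * 0.95 / 400) - 1e-9)
  expect_lt(mean(rej), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 400) + 1e-9)
})

test_that("paired Cohen's d follows the mean/SD-of-differences definition", {
  # differences (1, 2, 3, 4): d = 2.5 / 1.2910 ~ 1.936
  expect_equal(cohens_d_paired(1:4 + c(1, 2, 3, 4), 1:4),
               mean(c(1, 2, 3, 4)) / sd(c(1, 2, 3, 4)))
  expect_equal(round(cohens_d_paired(c(1, 2, 3, 4), rep(0, 4)), 3), 1.936)
  set.seed(6)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(cohens_d_paired(x, x), 0)
  expect_equal(cohens_d_paired(x, y), mean(x - y) / sd(x - y))
})

test_that("degenerate effect sizes error as specified", {
  expect_error(cohens_d_paired(1:4 + 2, 1:4), "zero SD")
  expect_equal(cohens_d_paired(c(1, 2, 3), c(1, 2, 2)),
               mean(c(0, 0, 1)) / sd(c(0, 0, 1)))
})

test_that("behavioural statistics match independent textbook computations", {
  set.seed(25)
  counts <- data.frame(auditory = rpois(16, 244), visual = rpois(16, 242))
  bp <- matrix(abs(rnorm(32)), 16)
  pc <- matrix(runif(32, 0.9, 1), 16)
  bs <- behavior_stats(counts, bp, pc)
  ref_t <- t.test(counts$auditory, counts$visual, paired = TRUE)
  expect_equal(bs$paired_t, unname(ref_t$statistic))
  expect_equal(bs$df, 15)
  expect_equal(bs$p, ref_t$p.value)
  d <- counts$auditory - counts$visual
  expect_equal(bs$d, mean(d) / sd(d))
  r_ref <- cor(bp[, 1], pc[, 1])
  n <- 16
  t_r <- r_ref * sqrt((n - 2) / (1 - r_ref^2))
  p_ref <- 2 * pt(-abs(t_r), n - 2)
  expect_equal(bs$power_performance$auditory$r, r_ref)
  expect_equal(bs$power_performance$auditory$p, p_ref, tolerance = 1e-10)

  same <- data.frame(auditory = counts$auditory, visual = counts$auditory)
  bs0 <- behavior_stats(same, bp, pc)
  expect_equal(bs0$paired_t, 0)

  lin <- bp; lin[, 1] <- pc[, 1] * 2 + 1  # perfectly linear relation
  expect_equal(behavior_stats(counts, lin, pc)$power_performance$auditory$r,
               1)
})
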