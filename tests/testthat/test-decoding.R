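test_that("feature matrices carry the band's integer-Hz bins and aligned labels", {
  set.seed(2)
  sp <- list(freqs = 4:25, power = matrix(abs(rnorm(22 * 6)), 22))
  labels <- c("auditory", "visual", "auditory", "visual", "auditory",
              "visual")
  th <- build_features(sp, labels, "theta")
  expect_equal(ncol(th$x), 4)
  expect_equal(colnames(th$x), paste0("f", 5:8))
  expect_equal(ncol(build_features(sp, labels, "broadband")$x), 22)
  expect_equal(ncol(build_features(sp, labels, "alpha")$x), 5)
  expect_equal(ncol(build_features(sp, labels, "beta")$x), 11)
  expect_equal(as.character(th$y), labels)
  expect_equal(unname(th$x[3, 2]), sp$power[which(4:25 == 6), 3])
  sp_bad <- list(freqs = 9:25, power = matrix(1, 17, 6))
  expect_error(build_features(sp_bad, labels, "theta"), "missing bins")
})

test_that("standardization yields zero mean and unit variance in both conventions", {
  x <- matrix(c(1, 2, 3), ncol = 1)
  expect_equal(as.numeric(standardize_features(x, "sample")), c(-1, 0, 1))
  expect_equal(as.numeric(standardize_features(x, "population")),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  set.seed(7)
  m <- matrix(rnorm(60, 5, 3), 20)
  z <- standardize_features(m)
  expect_equal(colMeans(z), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), rep(1, 3), tolerance = 1e-12)
  expect_equal(standardize_features(z), z, tolerance = 1e-12)
  expect_error(standardize_features(cbind(m, 7)), "zero-variance")
})

test_that("the k grid spans odd counts from 1 to a tenth of the trials", {
  expect_equal(make_k_grid(488), seq(1L, 47L, 2L))
  expect_length(make_k_grid(488), 24)
  expect_equal(make_k_grid(100), c(1L, 3L, 5L, 7L, 9L))
  expect_equal(make_k_grid(20), 1L)
  expect_equal(make_k_grid(9), 1L)
  expect_true(all(make_k_grid(1000) %% 2 == 1))
})

test_that("kNN prediction equals brute-force distance sorting on random toy sets", {
  set.seed(31)
  for (rep_i in 1:6) {
    n_train <- sample(10:30, 1)
    train_x <- matrix(rnorm(n_train * 3), n_train)
    train_y <- sample(c("a", "v"), n_train, replace = TRUE)
    while (length(unique(train_y)) < 2)
      train_y <- sample(c("a", "v"), n_train, replace = TRUE)
    test_x <- matrix(rnorm(8 * 3), 8)
    for (k in c(1L, 3L, 5L)) {
      expect_equal(knn_predict(train_x, train_y, test_x, k),
                   oracle_knn(train_x, train_y, test_x, k))
    }
  }
})

test_that("kNN honours its contracts at the boundaries", {
  train_x <- matrix(c(0, 0, 1, 1, 5, 5, 6, 6, 7, 7), ncol = 2, byrow = TRUE)
  train_y <- c("a", "a", "v", "v", "v")
  # test point identical to a training point, k = 1
  expect_equal(as.character(knn_predict(train_x, train_y,
                                        train_x[1, , drop = FALSE], 1L)),
               "a")
  # k = n_train: global majority everywhere
  far <- matrix(c(100, 100, -50, 3), ncol = 2, byrow = TRUE)
  expect_equal(as.character(knn_predict(train_x, train_y, far, 5L)),
               c("v", "v"))
  expect_error(knn_predict(train_x, train_y, far, 2L), "odd")
  expect_error(knn_predict(train_x, train_y, far, 7L), "training size")
})

test_that("grid search scores candidates by stratified shuffled CV and prefers small k", {
  set.seed(15)
  # perfectly separated classes: k = 1 reaches accuracy 1
  x <- rbind(matrix(rnorm(40, 0, 0.1), 20), matrix(rnorm(40, 10, 0.1), 20))
  y <- rep(c("a", "v"), each = 20)
  gs <- grid_search_k(x, y, grid = c(1L, 3L), seed = 2)
  expect_equal(unname(gs$scores["1"]), 1)
  expect_equal(gs$best_k, 1L)

  # label-independent features: ties resolved toward the smallest k
  xn <- matrix(rnorm(200), 100)
  yn <- rep(c("a", "v"), 50)
  gs_n <- grid_search_k(xn, yn, seed = 3)
  best_score <- max(gs_n$scores)
  smallest_max <- as.integer(names(gs_n$scores)[which(gs_n$scores ==
                                                        best_score)[1]])
  expect_equal(gs_n$best_k, smallest_max)
  expect_true(all(abs(gs_n$scores - 0.5) < 0.2))

  # selected k matches an exhaustive re-evaluation with the same folds
  x12 <- matrix(rnorm(24), 12)
  y12 <- rep(c("a", "v"), 6)
  gs12 <- grid_search_k(x12, y12, grid = c(1L, 3L, 5L), seed = 9)
  ref <- sapply(c(1L, 3L, 5L), function(k) {
    correct <- 0
    for (f in 1:2) {
      tr <- gs12$fold != f
      pred <- oracle_knn(x12[tr, , drop = FALSE], y12[tr],
                         x12[!tr, , drop = FALSE], k)
      correct <- correct + sum(pred == y12[!tr])
    }
    correct / 12
  })
  expect_equal(unname(gs12$scores), ref)
  expect_equal(gs12$best_k, c(1L, 3L, 5L)[which.max(ref)])
})

test_that("permutation decoding fixes k, reports add-one p and a fair chance level", {
  set.seed(44)
  x <- rbind(matrix(rnorm(60, 0, 0.1), 30), matrix(rnorm(60, 8, 0.1), 30))
  y <- rep(c("a", "v"), each = 30)
  pd <- permutation_decode(x, y, best_k = 1L, n_permutations = 200, seed = 5)
  expect_equal(pd$observed_accuracy, 1)
  expect_equal(pd$p_value, 1 / 201)
  expect_equal(pd$chance_level, mean(pd$permutation_scores))
  expect_gte(min(pd$permutation_scores), 0)
  expect_lte(max(pd$permutation_scores), 1)

  # label-independent features: chance close to 0.5 on balanced labels
  xn <- matrix(rnorm(300), 150)
  yn <- rep(c("a", "v"), 75)
  pdn <- permutation_decode(xn, yn, best_k = 7L, n_permutations = 300,
                            seed = 6)
  expect_lt(abs(pdn$chance_level - 0.5), 0.02)
  expect_gt(pdn$p_value, 0.01)
  expect_error(permutation_decode(xn, yn, best_k = 2L, 10), "odd")
})

test_that("decoding is deterministic under fixed seeds", {
  set.seed(1)
  x <- matrix(rnorm(200), 100)
  y <- rep(c("a", "v"), 50)
  g1 <- grid_search_k(x, y, seed = 11)
  g2 <- grid_search_k(x, y, seed = 11)
  expect_identical(g1, g2)
  p1 <- permutation_decode(x, y, g1$best_k, 50, seed = 12)
  p2 <- permutation_decode(x, y, g1$best_k, 50, seed = 12)
  expect_identical(p1$permutation_scores, p2$permutation_scores)
  expect_identical(p1$observed_accuracy, p2$observed_accuracy)
})

test_that("group statistics decompose band x type with the expected df", {
  set.seed(61)
  subs <- sprintf("S%02d", 1:16)
  grid <- expand.grid(subject = subs, foi = foi_names(),
                      type = c("observed", "chance"),
                      stringsAsFactors = FALSE)
  base <- rnorm(16, 0.5, 0.01)[match(grid$subject, subs)]

  # constant +0.03 offset for observed: large Type effect, tiny FOI and
  # interaction effects
  grid$accuracy <- base + ifelse(grid$type == "observed", 0.03, 0) +
    rnorm(nrow(grid), 0, 0.002)
  gs <- group_decoding_stats(grid)
  tab <- gs$anova
  expect_equal(tab$df1[tab$effect == "foi"], 3)
  expect_equal(tab$df2[tab$effect == "foi"], 45)
  expect_equal(tab$df1[tab$effect == "type"], 1)
  expect_equal(tab$df2[tab$effect == "type"], 15)
  expect_equal(tab$df1[tab$effect == "foi:type"], 3)
  expect_equal(tab$df2[tab$effect == "foi:type"], 45)
  expect_gt(tab$F[tab$effect == "type"], 50)
  expect_lt(tab$F[tab$effect == "foi"], 5)
  expect_lt(tab$F[tab$effect == "foi:type"], 5)
  expect_gt(tab$pes[tab$effect == "type"], 0.7)
  expect_gt(gs$per_foi$broadband$t, 5)
  expect_equal(gs$per_foi$broadband$df, 15)

  # observed identical to chance: all per-band t are 0 by convention
  grid0 <- grid
  grid0$accuracy <- base
  gs0 <- group_decoding_stats(grid0)
  expect_true(all(sapply(gs0$per_foi, function(e) e$t) == 0))

  expect_error(group_decoding_stats(grid[-1, ]), "complete")

  sp <- data.frame(subject = rep(subs, each = 4), foi = foi_names(),
                   p = 0.5)
  sp$p[sp$subject %in% subs[1:12] & sp$foi == "theta"] <- 0.01
  expect_equal(group_decoding_stats(grid, sp)$n_subjects_above_chance, 12)
})

test_that("pooled ANOVA partial eta squared matches the SS decomposition", {
  set.seed(71)
  subs <- sprintf("S%02d", 1:8)
  grid <- expand.grid(subject = subs, foi = foi_names(),
                      type = c("observed", "chance"),
                      stringsAsFactors = FALSE)
  grid$accuracy <- runif(nrow(grid), 0.4, 0.6)
  tab <- group_decoding_stats(grid)$anova
  fit <- stats::aov(accuracy ~ foi * type +
                      Error(factor(subject) / (factor(foi) * factor(type))),
                    data = grid)
  # independent recomputation of partial eta^2 for the type effect
  sm <- summary(fit)
  st <- sm[["Error: factor(subject):factor(type)"]][[1]]
  pes_ref <- st["type", "Sum Sq"] /
    (st["type", "Sum Sq"] + st["Residuals", "Sum Sq"])
  expect_equal(tab$pes[tab$effect == "type"], pes_ref, tolerance = 1e-10)
})
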