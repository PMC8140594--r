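# k-fold protocol, ROC/AUC, and top-fraction TPR.

test_that("kfold_split partitions positives into near-equal disjoint folds", {
  lm <- matrix(0, 5, 4); lm[1:10] <- 1
  f <- kfold_split(lm, 5, seed = 1)
  expect_length(f, 5L)
  expect_equal(lengths(f), rep(2L, 5), ignore_attr = TRUE)
  expect_setequal(unlist(f), which(lm == 1))

  lm2 <- matrix(0, 11, 2); lm2[1:11] <- 1
  f2 <- kfold_split(lm2, 5, seed = 2)
  expect_equal(sort(lengths(f2), decreasing = TRUE),
               c(3L, 2L, 2L, 2L, 2L), ignore_attr = TRUE)
  expect_equal(length(unlist(f2)), 11L)
  expect_equal(length(unique(unlist(f2))), 11L)

  expect_identical(kfold_split(lm, 3, seed = 7), kfold_split(lm, 3, seed = 7))
  expect_error(kfold_split(matrix(c(1, 0), 1), 5), "exceeds")
})

test_that("roc_auc matches hand-worked toys including reversal and ties", {
  expect_equal(roc_auc(c(3, 2, 1), c(1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 0, 0))$auc, 0.0)
  expect_equal(roc_auc(c(2, 2, 1, 1), c(1, 0, 1, 0))$auc, 0.5)
  expect_equal(roc_auc(rep(1, 6), c(1, 1, 0, 0, 0, 1))$auc, 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "positive and one negative")
})

test_that("roc_auc equals the exhaustive pair-counting oracle on random vectors", {
  set.seed(17)
  for (rep in 1:300) {
    n <- sample(2:12, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(1:4, n, replace = TRUE) + sample(c(0, 0.5), n, replace = TRUE)
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("the ROC polygon integrates to the U-statistic AUC", {
  set.seed(23)
  scores <- sample(1:5, 40, replace = TRUE)
  labels <- rbinom(40, 1, 0.4)
  ra <- roc_auc(scores, labels)
  trap <- sum(diff(ra$roc$fpr) *
              (utils::head(ra$roc$tpr, -1) + utils::tail(ra$roc$tpr, -1)) / 2)
  expect_equal(trap, ra$auc, tolerance = 1e-12)
  expect_equal(ra$roc$fpr[1], 0)
  expect_equal(utils::tail(ra$roc$tpr, 1), 1)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(29)
  scores <- rnorm(50)
  labels <- rbinom(50, 1, 0.5)
  a0 <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a0)
  expect_equal(roc_auc(2 * scores - 7, labels)$auc, a0)
})

test_that("top_fraction_tpr counts overlap in the top slice", {
  # 100 candidates, 4 positives of which 3 sit in the top 20 scores
  scores <- c(seq(100, 81), seq(80, 1))
  labels <- rep(0, 100)
  labels[c(1, 5, 20, 90)] <- 1
  expect_equal(top_fraction_tpr(scores, labels, 0.2), 0.75)
  expect_equal(top_fraction_tpr(scores, labels, 1), 1.0)
  labels2 <- rep(0, 100); labels2[1:4] <- 1
  expect_equal(top_fraction_tpr(scores, labels2, 0.05), 1.0)
})

test_that("run_cv reproduces a manually masked fold and never leaks test links", {
  bn <- toy_bilayer(seed = 16, n_lnc = 30, n_mi = 10)
  cv <- run_cv(bn, k = 3, t = 2, n_repeats = 1, seed = 5)
  # replay the internal seed fan-out
  set.seed(5)
  rep_seed <- sample.int(.Machine$integer.max, 1)
  set.seed(rep_seed)
  fold_seeds <- sample.int(.Machine$integer.max, 4)
  folds <- kfold_split(bn$lm, 3, seed = fold_seeds[4])
  lm_masked <- bn$lm
  lm_masked[folds[[1]]] <- 0
  expect_true(all(lm_masked[folds[[1]]] == 0))          # mask verified
  bn_masked <- bilayer_network(bn$A[1:30, 1:30], bn$A[31:40, 31:40], lm_masked)
  fit <- spmlmi(bn_masked, t = 2, fraction = 0.1, seed = fold_seeds[1])
  blk <- interaction_block(bn_masked, fit$scores)
  idx <- c(folds[[1]], which(bn$lm == 0))
  lab <- rep(c(1, 0), c(length(folds[[1]]), sum(bn$lm == 0)))
  expect_equal(cv$auc[1, 1], roc_auc(blk[idx], lab)$auc, tolerance = 1e-12)
})

test_that("run_cv is seed-reproducible and bounded", {
  bn <- toy_bilayer(seed = 17, n_lnc = 30, n_mi = 10)
  cv1 <- run_cv(bn, k = 3, t = 2, n_repeats = 2, seed = 9)
  cv2 <- run_cv(bn, k = 3, t = 2, n_repeats = 2, seed = 9)
  expect_identical(cv1$auc, cv2$auc)
  expect_true(all(cv1$auc >= 0 & cv1$auc <= 1))
  expect_equal(cv1$auc_mean, mean(cv1$auc))
  expect_output(print(cv1), "cross-validation")
})
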