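# Perturbation sampling and the first-order spectral correction.

test_that("sample_perturbation conserves A = A_R + dA with disjoint supports", {
  bn <- toy_bilayer(seed = 2, n_lnc = 30, n_mi = 10)
  set.seed(1)
  ps <- sample_perturbation(bn, fraction = 0.1)
  expect_identical(ps$a_r + ps$d_a, bn$A)               # exact conservation
  expect_true(all(ps$a_r[ps$d_a != 0] == 0))            # disjoint supports
  expect_identical(ps$d_a, t(ps$d_a))
  expect_true(nrow(ps$removed) > 0)
})

test_that("per-layer sampling removes round(fraction * L) links from each link kind", {
  bn <- toy_bilayer(seed = 3, n_lnc = 30, n_mi = 10)
  n_sim <- sum(bn$A[1:30, 1:30] != 0) / 2 + sum(bn$A[31:40, 31:40] != 0) / 2
  n_int <- sum(bn$lm != 0)
  set.seed(9)
  ps <- sample_perturbation(bn, fraction = 0.1)
  rem <- ps$removed
  is_int <- rem[, "i"] <= 30 & rem[, "j"] > 30
  expect_equal(sum(is_int), round(0.1 * n_int))
  expect_equal(sum(!is_int), round(0.1 * n_sim))

  # a layer of exactly 100 links loses exactly 10
  a <- er_graph(40, 100, seed = 5)
  set.seed(2)
  ps2 <- sample_perturbation(a, fraction = 0.1)
  expect_equal(nrow(ps2$removed), 10L)
})

test_that("removal counts that round to zero warn (or skip when min_one = FALSE)", {
  a <- path_graph(5)   # 4 links; 0.1 * 4 rounds to 0
  set.seed(1)
  expect_warning(ps <- sample_perturbation(a, fraction = 0.1), "removing 1 link")
  expect_equal(nrow(ps$removed), 1L)
  ps0 <- sample_perturbation(a, fraction = 0.1, min_one = FALSE)
  expect_identical(ps0$a_r, a)
  expect_true(all(ps0$d_a == 0))
  expect_error(sample_perturbation(a, fraction = 1), "< 1")
})

test_that("removed set matches an enumeration of the seeded generator draws", {
  a <- er_graph(5, 8, seed = 7)
  set.seed(123)
  ps <- sample_perturbation(a, fraction = 0.5)
  # oracle: replay the same draw against the enumerated link list
  pairs <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
  set.seed(123)
  expected <- pairs[sample.int(nrow(pairs), round(0.5 * nrow(pairs))), , drop = FALSE]
  expect_equal(unname(ps$removed), unname(expected))
})

test_that("zero perturbation reconstructs A_R to high relative accuracy", {
  for (seed in 1:20) {
    a <- rand_sym(15, seed)
    zero <- matrix(0, 15, 15)
    at <- first_order_perturb(a, zero)
    expect_lt(norm(at - a, "2") / norm(a, "2"), 1e-8)
  }
})

test_that("first_order_perturb matches the projector/rank-1-sum oracle", {
  # path graph with one removed edge, checked entrywise
  a <- path_graph(3)
  d <- matrix(0, 3, 3); d[2, 3] <- d[3, 2] <- 1
  expect_equal(first_order_perturb(a - d, d), oracle_first_order(a - d, d),
               tolerance = 1e-10)
  # random weighted matrices
  for (seed in 1:10) {
    a_r <- rand_sym(10, seed)
    d_a <- rand_sym(10, seed + 1000) * 0.2
    expect_equal(first_order_perturb(a_r, d_a), oracle_first_order(a_r, d_a),
                 tolerance = 1e-10)
  }
})

test_that("subspace handling is required under degeneracy and matches the oracle there", {
  # two disjoint cliques: heavily degenerate spectrum
  a <- clique_graph(2, 4)
  d <- matrix(0, 8, 8); d[1, 2] <- d[2, 1] <- 1
  at <- first_order_perturb(a - d, d)
  expect_equal(at, oracle_first_order(a - d, d), tolerance = 1e-10)
  expect_identical(at, t(at))
})

test_that("eigenvalue error of the first-order update scales quadratically", {
  a_r <- rand_sym(12, seed = 31)
  d_a <- rand_sym(12, seed = 32)
  err <- vapply(c(0.1, 0.01), function(eps) {
    at <- first_order_perturb(a_r, eps * d_a)
    max(abs(eigen(at, symmetric = TRUE, only.values = TRUE)$values -
            eigen(a_r + eps * d_a, symmetric = TRUE, only.values = TRUE)$values))
  }, numeric(1))
  ratio <- err[1] / err[2]
  expect_gt(ratio, 30)
  expect_lt(ratio, 300)
})
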