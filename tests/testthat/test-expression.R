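# Expression loading, standardization, and Pearson similarity.

test_that("read_expression drops incomplete rows, collapses duplicates, filters", {
  tf <- write_lines_tmp(c("id\tc1\tc2\tc3",
                          "L1\t1\t2\t3",
                          "L2\t4\t\t6",
                          "L3\t7\t8\t9",
                          "L4\t0\t1\t0"))
  expect_message(x <- read_expression(tf), "dropped 1 row")
  expect_equal(rownames(x), c("L1", "L3", "L4"))
  expect_equal(unname(x["L1", ]), c(1, 2, 3))

  tf2 <- write_lines_tmp(c("id\tc1\tc2",
                           "A\t1\t2", "B\t3\t4", "A\t9\t9", "C\t5\t6", "D\t7\t8"))
  expect_warning(y <- read_expression(tf2), "duplicate")
  expect_equal(unname(y["A", ]), c(1, 2))  # first occurrence wins
  z <- suppressWarnings(read_expression(tf2, id_filter = c("D", "B")))
  expect_equal(rownames(z), c("B", "D"))   # file order preserved
  expect_error(suppressWarnings(read_expression(tf2, id_filter = "nope")),
               "no usable profiles")
})

test_that("read_expression reports malformed rows with their line number", {
  tf <- write_lines_tmp(c("id\tc1\tc2", "L1\t1\t2", "L2\t3\t4\t5"))
  expect_error(read_expression(tf), "line 3")
})

test_that("a compendium-shaped file (262 x 124) loads without loss", {
  set.seed(42)
  n <- 262; m <- 124
  vals <- matrix(round(rexp(n * m), 4), n)
  lines <- c(paste(c("id", sprintf("t%03d", 1:m)), collapse = "\t"),
             vapply(1:n, function(i)
               paste(c(sprintf("hsa-miR-%04d", i), vals[i, ]), collapse = "\t"),
               character(1)))
  x <- read_expression(write_lines_tmp(lines))
  expect_equal(dim(x), c(262L, 124L))
  expect_equal(unname(x[17, ]), vals[17, ])
})

test_that("standardize_expression matches the closed-form z-score and is idempotent", {
  x <- rbind(a = c(1, 2, 3), b = c(10, 0, 5))
  z <- standardize_expression(x)
  expect_equal(unname(z["a", ]), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(unname(rowMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(rowMeans(z^2)), c(1, 1), tolerance = 1e-12)
  expect_equal(standardize_expression(z), z, tolerance = 1e-10)

  expect_warning(z2 <- standardize_expression(rbind(x, cc = c(5, 5, 5))),
                 "zero-variance")
  expect_equal(nrow(z2), 2L)
  expect_error(standardize_expression(rbind(k = c(2, 2, 2))), "degenerate")
})

test_that("expression_similarity matches a scalar Pearson oracle and its invariants", {
  set.seed(7)
  x <- matrix(rnorm(12), 3, 4, dimnames = list(c("r1", "r2", "r3"), NULL))
  s <- expression_similarity(x)
  # independent scalar evaluation of the Pearson formula
  for (i in 1:3) for (j in 1:3) {
    expected <- if (i == j) 0 else {
      a <- x[i, ] - mean(x[i, ]); b <- x[j, ] - mean(x[j, ])
      sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    }
    expect_equal(s[i, j], expected, tolerance = 1e-12)
  }
  expect_identical(s, t(s))               # exact symmetry, not tolerance
  expect_true(all(abs(s) <= 1 + 1e-12))

  dup <- rbind(a = c(1, 3, 2, 5), b = c(1, 3, 2, 5), cc = -c(1, 3, 2, 5))
  sd2 <- expression_similarity(dup)
  expect_equal(sd2["a", "b"], 1)
  expect_equal(sd2["a", "cc"], -1)
  expect_error(expression_similarity(rbind(a = c(1, 1, 1), b = c(1, 2, 3))),
               "zero-variance")
})

test_that("sparsify_similarity keeps the strongest entries and stays symmetric", {
  s <- rand_sym(12, seed = 3)
  sp <- sparsify_similarity(s, q = 25)
  kept <- sum(sp[upper.tri(sp)] != 0)
  expect_equal(kept, round(sum(upper.tri(s)) * 0.25))
  expect_identical(sp, t(sp))
  # kept entries are exactly the largest |weights|
  thr <- min(abs(sp[upper.tri(sp)][sp[upper.tri(sp)] != 0]))
  expect_true(all(abs(s[upper.tri(s)][sp[upper.tri(sp)] == 0]) < thr))
})
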