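# Independent oracles and small fixture builders used across tests.
# The oracles deliberately use different code paths (explicit loops,
# projector sums, pair counting) from the implementation they check.

# Brute-force first-order perturbation: explicit eigendecomposition, then a
# sum over eigenvalue clusters in basis-free projector form
#   sum_c [ lambda_c P_c + P_c dA P_c ],   P_c = sum_{k in c} x_k x_k^T.
# For a non-degenerate eigenvalue this reduces to the scalar formula
# (lambda_k + x_k' dA x_k) x_k x_k', i.e. the rank-1-sum oracle.
oracle_first_order <- function(a_r, d_a, tol = 1e-8) {
  e <- eigen(a_r, symmetric = TRUE)
  n <- nrow(a_r)
  thr <- tol * max(abs(e$values), tol)
  out <- matrix(0, n, n)
  k <- 1L
  while (k <= n) {
    grp <- k
    while (max(grp) < n && abs(e$values[max(grp) + 1L] - e$values[max(grp)]) <= thr)
      grp <- c(grp, max(grp) + 1L)
    p <- matrix(0, n, n)
    for (g in grp) p <- p + tcrossprod(e$vectors[, g])
    out <- out + e$values[k] * p + p %*% d_a %*% p
    k <- max(grp) + 1L
  }
  out
}

# Exhaustive Mann-Whitney AUC with half credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Adjacency matrix of an undirected path graph on n nodes.
path_graph <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) a[i, i + 1L] <- a[i + 1L, i] <- 1
  a
}

# Disjoint cliques of size `m` (r of them) as one adjacency matrix.
clique_graph <- function(r, m) {
  a <- matrix(0, r * m, r * m)
  for (b in seq_len(r)) {
    idx <- (b - 1L) * m + seq_len(m)
    a[idx, idx] <- 1
  }
  diag(a) <- 0
  a
}

# Erdos-Renyi symmetric graph with exactly `l` links.
er_graph <- function(n, l, seed) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  take <- pairs[sample.int(nrow(pairs), l), , drop = FALSE]
  a <- matrix(0, n, n)
  a[take] <- 1
  a[take[, 2:1, drop = FALSE]] <- 1
  a
}

# Tiny random symmetric weighted matrix with zero diagonal.
rand_sym <- function(n, seed) {
  set.seed(seed)
  a <- matrix(rnorm(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

# Standard strongly structured bilayer used by pipeline-level tests.
toy_bilayer <- function(seed = 1, n_lnc = 60, n_mi = 20) {
  sim <- simulate_lmi_data(n_lnc = n_lnc, n_mi = n_mi, seed = seed)
  bilayer_network(
    expression_similarity(standardize_expression(sim$lnc_expr)),
    expression_similarity(standardize_expression(sim$mi_expr)),
    sim$interactions)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  tf <- tempfile(fileext = ext)
  writeLines(lines, tf)
  tf
}
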