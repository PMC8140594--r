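# The structural perturbation method: perturbation-set sampling and the
# first-order spectral correction.

#' Sample a perturbation link set
#'
#' Randomly removes a fraction of the links of a network, returning the
#' reduced matrix `a_r`, the removed-links matrix `d_a` (so that
#' `a_r + d_a` reproduces the original entrywise) and the removed index
#' pairs. For a bilayer network the two kinds of links — similarity links
#' (both similarity blocks pooled) and interaction links — are sampled
#' independently, each losing `round(fraction * L)` of its `L` links.
#' Removal zeroes both `(i,j)` and `(j,i)`.
#'
#' Draws from the current RNG state; call `set.seed()` for reproducibility.
#'
#' @param x A `bilayer_network` or a symmetric numeric matrix (treated as a
#'   single layer).
#' @param fraction Proportion of links to remove per layer, in (0, 1).
#' @param per_layer Sample each link kind independently (default `TRUE` for
#'   bilayer networks; ignored for single matrices). `FALSE` pools all
#'   links.
#' @param min_one If a layer's removal count rounds to 0, remove 1 link
#'   from it with a warning (default). With `min_one = FALSE` the layer is
#'   left untouched, so a vanishing fraction gives an empty removal.
#' @return An object of class `perturbation_sample`: list with `a_r`,
#'   `d_a`, `removed` (2-column index matrix, i < j), `fraction`.
#' @export
sample_perturbation <- function(x, fraction = 0.1, per_layer = TRUE,
                                min_one = TRUE) {
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0)
    stop_spmlmi("'fraction' must be a scalar in (0, 1)")
  if (fraction >= 1) stop_spmlmi("'fraction' must be < 1")
  a <- if (inherits(x, "bilayer_network")) x$A else x
  check_symmetric(a, "x")
  n <- nrow(a)

  pairs <- upper_pairs(a)
  if (nrow(pairs) == 0L) stop_spmlmi("network has no links")
  if (inherits(x, "bilayer_network") && per_layer) {
    # similarity links live inside a diagonal block; interaction links cross
    in_lnc <- pairs[, "i"] <= x$n_lnc & pairs[, "j"] <= x$n_lnc
    in_mi <- pairs[, "i"] > x$n_lnc & pairs[, "j"] > x$n_lnc
    layer <- ifelse(in_lnc | in_mi, "similarity", "interaction")
    if (!any(layer == "similarity") || !any(layer == "interaction"))
      stop_spmlmi("each link kind needs at least one link for per-layer sampling")
  } else {
    layer <- rep("all", nrow(pairs))
  }

  take <- integer(0)
  for (lay in unique(layer)) {
    idx <- which(layer == lay)
    m <- round(fraction * length(idx))
    if (m == 0L) {
      if (!min_one) next
      warning(sprintf("removal count for %s links rounds to 0; removing 1 link",
                      lay), call. = FALSE)
      m <- 1L
    }
    take <- c(take, idx[sample.int(length(idx), m)])
  }
  removed <- pairs[take, , drop = FALSE]

  d_a <- matrix(0, n, n, dimnames = dimnames(a))
  d_a[removed] <- a[removed]
  d_a[removed[, 2:1, drop = FALSE]] <- a[removed]
  structure(list(a_r = a - d_a, d_a = d_a, removed = removed,
                 fraction = fraction),
            class = "perturbation_sample")
}

#' First-order structural perturbation of a reduced network
#'
#' Given the reduced adjacency `a_r` and the removed-links matrix `d_a`,
#' eigendecomposes \eqn{A_R = \sum_k \lambda_k x_k x_k^T}, corrects each
#' eigenvalue by \eqn{\Delta\lambda_k = x_k^T \Delta A\, x_k / (x_k^T x_k)}
#' while holding the eigenvectors fixed, and reconstructs the perturbed
#' matrix \eqn{\tilde A = \sum_k (\lambda_k + \Delta\lambda_k) x_k x_k^T}.
#' Entries of \eqn{\tilde A} score unobserved links.
#'
#' When eigenvalues are (numerically) degenerate the per-vector correction
#' is ill-defined: any basis of the eigenspace is an eigenbasis. The default
#' `"subspace"` handling applies degenerate first-order perturbation theory
#' — it diagonalizes \eqn{\Delta A} restricted to each degenerate eigenspace
#' and uses the resulting basis and corrections, which is basis-independent.
#' `"naive"` applies the per-vector formula to whatever basis the
#' eigensolver returned.
#'
#' @param a_r Symmetric reduced matrix, or a `perturbation_sample` (in which
#'   case `d_a` is taken from it).
#' @param d_a Symmetric removed-links matrix.
#' @param degenerate `"subspace"` (default) or `"naive"`.
#' @param tol Relative gap below which eigenvalues are treated as
#'   degenerate (`tol * max(|lambda|)`).
#' @return The symmetric perturbed matrix \eqn{\tilde A}.
#' @export
first_order_perturb <- function(a_r, d_a = NULL,
                                degenerate = c("subspace", "naive"),
                                tol = 1e-8) {
  if (inherits(a_r, "perturbation_sample")) {
    d_a <- a_r$d_a
    a_r <- a_r$a_r
  }
  degenerate <- match.arg(degenerate)
  check_symmetric(a_r, "a_r")
  check_symmetric(d_a, "d_a")
  if (nrow(a_r) != nrow(d_a)) stop_spmlmi("'a_r' and 'd_a' dimensions differ")

  e <- eigen(a_r, symmetric = TRUE)
  lam <- e$values            # descending
  vec <- e$vectors           # orthonormal columns
  dlam <- numeric(length(lam))

  if (degenerate == "naive") {
    dlam <- colSums(vec * (d_a %*% vec))
  } else {
    thr <- tol * max(abs(lam), tol)
    # consecutive eigenvalues closer than thr form one degenerate cluster
    cluster <- cumsum(c(1, diff(lam) < -thr | diff(lam) > thr))
    for (cl in unique(cluster)) {
      idx <- which(cluster == cl)
      v <- vec[, idx, drop = FALSE]
      s <- crossprod(v, d_a %*% v)
      if (length(idx) == 1L) {
        dlam[idx] <- s[1L]
      } else {
        s <- (s + t(s)) / 2
        es <- eigen(s, symmetric = TRUE)
        vec[, idx] <- v %*% es$vectors
        dlam[idx] <- es$values
      }
    }
  }
  out <- vec %*% ((lam + dlam) * t(vec))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(a_r)
  out
}
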