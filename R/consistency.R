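# Structural consistency: how well perturbation scores recover a randomly
# removed link set — a data-driven index of a network's link predictability.

sigma_one_rep <- function(net, fraction, universe, degenerate) {
  ps <- sample_perturbation(net, fraction = fraction,
                            per_layer = inherits(net, "bilayer_network"))
  a_tilde <- first_order_perturb(ps, degenerate = degenerate)
  a_r <- ps$a_r
  removed <- ps$removed

  if (universe == "interaction") {
    if (!inherits(net, "bilayer_network"))
      stop_spmlmi("universe = 'interaction' needs a bilayer network")
    n_lnc <- net$n_lnc
    cross <- removed[, "i"] <= n_lnc & removed[, "j"] > n_lnc
    removed <- removed[cross, , drop = FALSE]
    cand <- upper_pairs(a_r, nonzero = FALSE)
    cand <- cand[cand[, "i"] <= n_lnc & cand[, "j"] > n_lnc, , drop = FALSE]
  } else {
    cand <- upper_pairs(a_r, nonzero = FALSE)
  }
  l <- nrow(removed)
  if (l == 0L) stop_spmlmi("perturbation removed no links in the scored universe")
  if (nrow(cand) < l)
    stop_spmlmi(sprintf("candidate pool (%d) smaller than removed set (%d)",
                        nrow(cand), l))
  sc <- a_tilde[cand]
  top <- cand[order(-sc, cand[, "i"], cand[, "j"])[seq_len(l)], , drop = FALSE]
  key <- function(p) p[, "i"] * (nrow(a_r) + 1) + p[, "j"]
  sum(key(top) %in% key(removed)) / l
}

#' Structural-consistency index of a network
#'
#' Repeatedly removes a random `fraction` of the links, scores the
#' remaining network's non-link entries with the first-order perturbed
#' matrix, and measures the fraction of removed links recovered among the
#' top-L scores (L = number of removed links). The index lies in \[0, 1\];
#' values far above the random-overlap baseline indicate a network whose
#' structure makes its links intrinsically predictable.
#'
#' Dense similarity networks have no non-link entries, so the index is
#' undefined on them; sparsify first with [sparsify_similarity()] (see
#' [compare_layers()], which does this consistently for all layers).
#'
#' @param net A `bilayer_network` (links of each kind are removed
#'   independently) or a symmetric matrix with at least one zero
#'   off-diagonal entry.
#' @param fraction Proportion of links removed per repetition (default
#'   0.10).
#' @param n_reps Number of independent repetitions (default 10).
#' @param seed Optional integer seed.
#' @param universe Candidate universe for a bilayer: `"all"` non-link
#'   entries across both layers (default), or `"interaction"` to restrict
#'   scoring and recovery to the interaction block (ablation).
#' @param degenerate Passed to [first_order_perturb()].
#' @return Object of class `structural_consistency`: list with
#'   `sigma_mean`, `sigma_sd`, `per_rep`, `n_reps`, `fraction`.
#' @export
structural_consistency <- function(net, fraction = 0.1, n_reps = 10,
                                   seed = NULL,
                                   universe = c("all", "interaction"),
                                   degenerate = c("subspace", "naive")) {
  universe <- match.arg(universe)
  degenerate <- match.arg(degenerate)
  if (n_reps < 1) stop_spmlmi("'n_reps' must be >= 1")
  a <- if (inherits(net, "bilayer_network")) net$A else net
  check_symmetric(a, "net")
  if (!inherits(net, "bilayer_network") &&
      nrow(upper_pairs(a, nonzero = FALSE)) == 0L)
    stop_spmlmi(paste("network has no non-link entries; apply",
                      "sparsify_similarity() to dense similarity networks"))
  seeds <- child_seeds(n_reps, seed)
  per_rep <- vapply(seq_len(n_reps), function(r) {
    set.seed(seeds[r])
    sigma_one_rep(net, fraction, universe, degenerate)
  }, numeric(1))
  structure(list(sigma_mean = mean(per_rep),
                 sigma_sd = if (n_reps > 1) stats::sd(per_rep) else 0,
                 per_rep = per_rep, n_reps = n_reps, fraction = fraction,
                 universe = universe),
            class = "structural_consistency")
}

#' @export
print.structural_consistency <- function(x, ...) {
  cat(sprintf("Structural consistency: %.4f +/- %.4f (%d reps, %.0f%% removal)\n",
              x$sigma_mean, x$sigma_sd, x$n_reps, 100 * x$fraction))
  invisible(x)
}

#' Compare structural consistency across layers and the bilayer
#'
#' Computes the structural-consistency index for the lncRNA similarity
#' layer, the miRNA similarity layer, and the bilayer combining both with
#' the interaction layer. The standalone similarity networks are
#' sparsified to their top-`q`% strongest entries first — a dense
#' correlation network has no non-link entries, so the index is undefined
#' on it. The bilayer is used as given (its similarity blocks stay dense
#' when dense matrices are passed), matching how it enters prediction.
#'
#' @param ls,ms Symmetric similarity matrices (dense allowed; sparsified
#'   internally).
#' @param lm Binary interaction matrix aligned with `ls` and `ms`.
#' @param fraction,n_reps,seed,degenerate As [structural_consistency()].
#' @param q Sparsification percentage passed to [sparsify_similarity()].
#' @return A data frame with one row per network (`LSnet`, `MSnet`,
#'   `Bilayer-net`) and columns `sigma_mean`, `sigma_sd`, `n_reps`,
#'   `fraction`; the full `structural_consistency` objects are attached as
#'   attribute `"results"`.
#' @export
compare_layers <- function(ls, ms, lm, fraction = 0.1, n_reps = 10,
                           seed = NULL, q = 10,
                           degenerate = c("subspace", "naive")) {
  degenerate <- match.arg(degenerate)
  ls_s <- sparsify_similarity(ls, q)
  ms_s <- sparsify_similarity(ms, q)
  bn <- bilayer_network(ls, ms, lm)
  seeds <- child_seeds(3L, seed)
  res <- list(
    "LSnet" = structural_consistency(ls_s, fraction, n_reps, seeds[1L],
                                     degenerate = degenerate),
    "MSnet" = structural_consistency(ms_s, fraction, n_reps, seeds[2L],
                                     degenerate = degenerate),
    "Bilayer-net" = structural_consistency(bn, fraction, n_reps, seeds[3L],
                                           degenerate = degenerate))
  out <- data.frame(network = names(res),
                    sigma_mean = vapply(res, `[[`, numeric(1), "sigma_mean"),
                    sigma_sd = vapply(res, `[[`, numeric(1), "sigma_sd"),
                    n_reps = n_reps, fraction = fraction,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "results") <- res
  out
}
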