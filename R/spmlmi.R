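# The SPMLMI fit: averaged structural-perturbation score matrix over a
# bilayer network, with the usual modelling-object methods.

#' Fit a structural-perturbation link-prediction model
#'
#' Draws `t` independent perturbation sets from the observed network,
#' computes the first-order perturbed matrix for each, and averages them
#' into a score matrix whose entries rank candidate links: a higher score
#' means a more probable unobserved interaction.
#'
#' @param network A `bilayer_network` (see [bilayer_network()]) or any
#'   symmetric numeric matrix.
#' @param t Number of independent perturbations to average (default 8;
#'   scores stabilize for `t` around 8 and beyond).
#' @param fraction Proportion of links removed per layer in each
#'   perturbation (default 0.10).
#' @param seed Optional integer seed; child seeds for the `t` perturbations
#'   are fanned out deterministically.
#' @param per_layer Sample similarity and interaction links independently
#'   (default `TRUE`; see [sample_perturbation()]).
#' @param degenerate Degenerate-eigenvalue handling passed to
#'   [first_order_perturb()].
#' @return An object of class `spmlmi`: list with the symmetric `scores`
#'   matrix, the `network`, and the call parameters.
#' @examples
#' sim <- simulate_lmi_data(n_lnc = 30, n_mi = 10, seed = 1)
#' bn <- bilayer_network(expression_similarity(standardize_expression(sim$lnc_expr)),
#'                       expression_similarity(standardize_expression(sim$mi_expr)),
#'                       sim$interactions)
#' fit <- spmlmi(bn, t = 4, seed = 1)
#' head(predict(fit), 3)
#' @export
spmlmi <- function(network, t = 8, fraction = 0.1, seed = NULL,
                   per_layer = TRUE, degenerate = c("subspace", "naive")) {
  degenerate <- match.arg(degenerate)
  if (!is.numeric(t) || length(t) != 1L || t < 1 || t != round(t))
    stop_spmlmi("'t' must be a positive integer")
  t <- as.integer(t)
  a <- if (inherits(network, "bilayer_network")) network$A else network
  check_symmetric(a, "network")

  seeds <- child_seeds(t, seed)
  scores <- matrix(0, nrow(a), ncol(a))
  for (r in seq_len(t)) {
    set.seed(seeds[r])
    ps <- sample_perturbation(network, fraction = fraction,
                              per_layer = per_layer)
    scores <- scores + first_order_perturb(ps, degenerate = degenerate)
  }
  scores <- scores / t
  dimnames(scores) <- dimnames(a)
  structure(list(scores = scores, network = network, t = t,
                 fraction = fraction, seed = seed, per_layer = per_layer,
                 degenerate = degenerate, call = match.call()),
            class = "spmlmi")
}

candidate_table <- function(object) {
  net <- object$network
  if (inherits(net, "bilayer_network")) {
    block <- interaction_block(net, object$scores)
    cand <- which(net$lm == 0, arr.ind = TRUE)
    data.frame(lnc_id = net$lnc_ids[cand[, 1L]],
               mi_id = net$mi_ids[cand[, 2L]],
               score = block[cand],
               i = cand[, 1L], j = cand[, 2L],
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    cand <- upper_pairs(net, nonzero = FALSE)
    ids <- rownames(net)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(net)))
    data.frame(lnc_id = ids[cand[, "i"]], mi_id = ids[cand[, "j"]],
               score = object$scores[cand],
               i = cand[, "i"], j = cand[, "j"],
               stringsAsFactors = FALSE, row.names = NULL)
  }
}

#' Rank candidate interactions from a fitted model
#'
#' Candidates are the entries of the interaction block that are 0 in the
#' observed interaction layer (for a plain symmetric network, all non-link
#' pairs). They are sorted by score, descending; ties are broken by
#' (lncRNA index, miRNA index) ascending so the ranking is deterministic.
#'
#' @param object A fitted `spmlmi` object.
#' @param query Optional node identifier; restricts candidates to that
#'   node's row or column (e.g. rank candidate miRNA partners of one
#'   lncRNA).
#' @param n Optional number of top candidates to return.
#' @param ... Unused.
#' @return A data frame with columns `lnc_id`, `mi_id`, `score`, `rank`.
#' @export
predict.spmlmi <- function(object, query = NULL, n = NULL, ...) {
  tab <- candidate_table(object)
  if (!is.null(query)) {
    keep <- tab$lnc_id == query | tab$mi_id == query
    if (!any(tab$lnc_id == query) && !any(tab$mi_id == query)) {
      net_ids <- if (inherits(object$network, "bilayer_network"))
        object$network$node_ids else rownames(object$network)
      if (!query %in% net_ids)
        stop_spmlmi(sprintf("query id '%s' not found in the network", query))
    }
    tab <- tab[keep, , drop = FALSE]
  }
  ord <- order(-tab$score, tab$i, tab$j)
  tab <- tab[ord, c("lnc_id", "mi_id", "score"), drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  if (!is.null(n)) tab <- utils::head(tab, n)
  tab
}

#' @export
print.spmlmi <- function(x, ...) {
  cat("Structural-perturbation link prediction fit\n")
  cat(sprintf("  t = %d perturbations, fraction = %.3g per layer\n",
              x$t, x$fraction))
  net <- x$network
  if (inherits(net, "bilayer_network")) {
    cat(sprintf("  network: %d lncRNAs + %d miRNAs, %d known interactions\n",
                net$n_lnc, net$n_mi, sum(net$lm != 0)))
  } else {
    cat(sprintf("  network: %d nodes\n", nrow(net)))
  }
  invisible(x)
}

#' @export
summary.spmlmi <- function(object, n_top = 5L, ...) {
  tab <- predict(object)
  net <- object$network
  known <- if (inherits(net, "bilayer_network")) {
    blk <- interaction_block(net, object$scores)
    blk[net$lm != 0]
  } else {
    object$scores[upper_pairs(net)]
  }
  out <- list(fit = object, top = utils::head(tab, n_top),
              known_scores = summary(known),
              candidate_scores = summary(tab$score))
  class(out) <- "summary.spmlmi"
  out
}

#' @export
print.summary.spmlmi <- function(x, ...) {
  print(x$fit)
  cat("\nScores on known links:\n")
  print(x$known_scores)
  cat("\nScores on candidate (unobserved) links:\n")
  print(x$candidate_scores)
  cat("\nTop candidates:\n")
  print(x$top)
  invisible(x)
}

#' Plot score separation of a fitted model
#'
#' Overlaid densities of scores on known links and on candidate
#' (unobserved) links; useful as a quick visual check that the perturbation
#' scores separate observed structure from background.
#'
#' @param x A fitted `spmlmi` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.spmlmi <- function(x, ...) {
  tab <- candidate_table(x)
  net <- x$network
  known <- if (inherits(net, "bilayer_network")) {
    blk <- interaction_block(net, x$scores)
    blk[net$lm != 0]
  } else {
    x$scores[upper_pairs(net)]
  }
  dc <- stats::density(tab$score)
  dk <- stats::density(known)
  graphics::plot(dc, xlim = range(dc$x, dk$x), ylim = range(0, dc$y, dk$y),
                 main = "Perturbation scores", xlab = "score", ...)
  graphics::lines(dk, col = 2)
  graphics::legend("topright", legend = c("candidates", "known links"),
                   col = c(1, 2), lty = 1, bty = "n")
  invisible(x)
}
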