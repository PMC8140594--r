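# k-fold cross-validation of interaction prediction with ROC/AUC, using the
# reset-and-rank protocol: held-out known interactions are reset to unknown,
# the model is refit on the masked bilayer, and candidate entries are ranked
# by score.

#' Partition known interactions into k folds
#'
#' Randomly partitions the positive (value 1) entries of an interaction
#' matrix into `k` disjoint subsets whose sizes differ by at most one.
#'
#' @param lm Binary interaction matrix.
#' @param k Number of folds (>= 2).
#' @param seed Optional integer seed.
#' @return A list of `k` integer vectors of linear indices into `lm`.
#' @export
kfold_split <- function(lm, k, seed = NULL) {
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k != round(k))
    stop_spmlmi("'k' must be an integer >= 2")
  pos <- which(lm == 1)
  if (length(pos) < k)
    stop_spmlmi(sprintf("k = %d exceeds the %d known interactions", k, length(pos)))
  if (!is.null(seed)) set.seed(seed)
  pos <- sample(pos)
  sizes <- rep(length(pos) %/% k, k) + (seq_len(k) <= length(pos) %% k)
  split(pos, rep(seq_len(k), times = sizes))
}

#' ROC curve and AUC
#'
#' Sweeps all distinct score thresholds and computes the receiver operating
#' characteristic; the area under it is computed by the trapezoidal rule,
#' which with tied scores equals the Mann-Whitney U statistic with half
#' credit for ties.
#'
#' @param scores Numeric score vector (higher = more positive).
#' @param labels Binary vector (1 = positive) of the same length.
#' @return List with `auc` (scalar) and `roc` (data frame of `fpr`, `tpr`
#'   including the (0,0) and (1,1) endpoints).
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop_spmlmi("'scores' and 'labels' lengths differ")
  labels <- as.integer(labels != 0)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_spmlmi("labels must contain at least one positive and one negative")
  r <- rank(scores)                       # midranks: ties get 0.5 credit
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  tp <- cumsum(labels[ord] == 1L)
  fp <- cumsum(labels[ord] == 0L)
  last <- which(c(s[-1L] != s[-length(s)], TRUE))  # last index of each tie group
  roc <- data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))
  list(auc = auc, roc = roc)
}

#' True-positive rate within the top-ranked fraction
#'
#' Ranks all scored entries in descending order and reports the proportion
#' of positives found among the top `round(frac * n)` entries — the overlap
#' statistic used alongside ROC in the reset-and-rank protocol (with
#' `frac = 1/k`).
#'
#' @param scores,labels As [roc_auc()].
#' @param frac Fraction of the ranking to inspect, in (0, 1].
#' @return Scalar in \[0, 1\].
#' @export
top_fraction_tpr <- function(scores, labels, frac) {
  if (length(scores) != length(labels))
    stop_spmlmi("'scores' and 'labels' lengths differ")
  if (!is.numeric(frac) || length(frac) != 1L || frac <= 0 || frac > 1)
    stop_spmlmi("'frac' must be in (0, 1]")
  labels <- as.integer(labels != 0)
  if (sum(labels) == 0L) stop_spmlmi("no positives in 'labels'")
  n_top <- round(frac * length(scores))
  top <- order(-scores, seq_along(scores))[seq_len(n_top)]
  sum(labels[top]) / sum(labels)
}

# One CV fold: mask the test positives in the interaction block, refit on
# the masked bilayer, and evaluate held-out positives against the original
# zero entries.
cv_one_fold <- function(bn, test_idx, t, fraction, seed, degenerate) {
  lm <- bn$lm
  lm_masked <- lm
  lm_masked[test_idx] <- 0
  bn_masked <- bilayer_network(
    bn$A[seq_len(bn$n_lnc), seq_len(bn$n_lnc), drop = FALSE],
    bn$A[bn$n_lnc + seq_len(bn$n_mi), bn$n_lnc + seq_len(bn$n_mi), drop = FALSE],
    lm_masked)
  fit <- spmlmi(bn_masked, t = t, fraction = fraction, seed = seed,
                degenerate = degenerate)
  block <- interaction_block(bn_masked, fit$scores)
  eval_idx <- c(test_idx, which(lm == 0))   # held-out positives + true unknowns
  labels <- c(rep(1L, length(test_idx)), rep(0L, sum(lm == 0)))
  list(scores = block[eval_idx], labels = labels)
}

#' Cross-validated evaluation of interaction prediction
#'
#' Repeated k-fold cross-validation of the full pipeline: per fold, the
#' held-out known interactions are reset to 0 in the interaction block (the
#' similarity blocks, which derive from expression only, are untouched),
#' the model is refit on the masked bilayer, and ROC/AUC is computed over
#' the held-out positives versus all entries that are 0 in the original
#' interaction matrix (training positives are excluded so memorization is
#' not rewarded).
#'
#' @param bn A `bilayer_network`.
#' @param k Number of folds (default 5).
#' @param t,fraction,degenerate Passed to [spmlmi()].
#' @param n_repeats Number of independent repetitions with fresh partitions
#'   (default 10).
#' @param seed Optional integer seed.
#' @return Object of class `spmlmi_cv`: `auc` (n_repeats x k matrix),
#'   `auc_mean`, `auc_sd` (over all folds and repeats), `tpr_topk`
#'   (top-1/k overlap TPR per fold), `roc` (list of per-fold ROC data
#'   frames for the first repeat), and the protocol parameters.
#' @export
run_cv <- function(bn, k = 5, t = 8, fraction = 0.1, n_repeats = 10,
                   seed = NULL, degenerate = c("subspace", "naive")) {
  degenerate <- match.arg(degenerate)
  if (!inherits(bn, "bilayer_network")) stop_spmlmi("'bn' must be a bilayer_network")
  if (n_repeats < 1) stop_spmlmi("'n_repeats' must be >= 1")
  rep_seeds <- child_seeds(n_repeats, seed)
  auc <- matrix(NA_real_, n_repeats, k)
  tpr <- matrix(NA_real_, n_repeats, k)
  roc1 <- vector("list", k)
  for (r in seq_len(n_repeats)) {
    fold_seeds <- child_seeds(k + 1L, rep_seeds[r])
    folds <- kfold_split(bn$lm, k, seed = fold_seeds[k + 1L])
    for (f in seq_len(k)) {
      if (length(folds[[f]]) == 0L) stop_spmlmi("fold with zero test positives")
      ev <- cv_one_fold(bn, folds[[f]], t, fraction, fold_seeds[f], degenerate)
      ra <- roc_auc(ev$scores, ev$labels)
      auc[r, f] <- ra$auc
      tpr[r, f] <- top_fraction_tpr(ev$scores, ev$labels, 1 / k)
      if (r == 1L) roc1[[f]] <- ra$roc
    }
  }
  structure(list(auc = auc, auc_mean = mean(auc), auc_sd = stats::sd(auc),
                 tpr_topk = tpr, roc = roc1, k = k, t = t,
                 fraction = fraction, n_repeats = n_repeats, seed = seed),
            class = "spmlmi_cv")
}

#' @export
print.spmlmi_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %d repeat(s), t = %d, fraction = %.3g\n",
              x$k, x$n_repeats, x$t, x$fraction))
  cat(sprintf("  AUC = %.4f +/- %.4f\n", x$auc_mean, x$auc_sd))
  cat(sprintf("  top-1/k TPR = %.4f +/- %.4f\n",
              mean(x$tpr_topk), stats::sd(x$tpr_topk)))
  invisible(x)
}

#' Plot cross-validated ROC curves
#'
#' Draws the per-fold ROC curves of the first repetition.
#'
#' @param x An `spmlmi_cv` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.spmlmi_cv <- function(x, ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("%d-fold CV ROC (AUC = %.3f)", x$k, x$auc_mean),
                 ...)
  for (f in seq_along(x$roc))
    graphics::lines(x$roc[[f]]$fpr, x$roc[[f]]$tpr, col = f)
  invisible(x)
}
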