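# Group-structured synthetic data: latent co-expression groups per RNA
# class plus a block-model interaction layer. This emulates the ceRNA
# premise — co-expressed lncRNAs tend to share miRNA partners — so every
# pipeline stage is testable without external databases.

default_affinity <- function(n_groups, diag_p = 0.6, background_p = 0.02) {
  a <- matrix(background_p, n_groups, n_groups)
  diag(a) <- diag_p
  a
}

group_labels <- function(n, n_groups) sort(rep_len(seq_len(n_groups), n))

#' Simulate group-structured expression profiles and interactions
#'
#' Each co-expression group receives a latent condition profile (iid
#' standard normal); each RNA's profile is its group profile plus iid
#' Gaussian noise of standard deviation `noise_sd`. Interactions are drawn
#' independently with probability `affinity[g, h]` for a lncRNA of group
#' `g` and an miRNA of group `h`. Group labels are assigned evenly and
#' deterministically, so group sizes differ by at most one.
#'
#' Defaults emulate the statistical shape of real lncRNA/miRNA expression
#' compendia at desk scale: 120 lncRNAs x 40 miRNAs (the ~12:1 ratio of the
#' public databases had 3,150 : 262), 24 conditions, 4 latent groups,
#' moderate noise, and a sparse interaction layer concentrated on matched
#' groups.
#'
#' @param n_lnc,n_mi Numbers of lncRNAs and miRNAs.
#' @param n_conditions Number of tissues / cell lines (>= 3).
#' @param n_groups Latent co-expression groups per RNA class.
#' @param noise_sd Within-group noise sd, relative to the unit group-signal
#'   sd.
#' @param affinity `n_groups` x `n_groups` matrix of interaction
#'   probabilities between lncRNA groups (rows) and miRNA groups (columns).
#'   Default: `background_p` everywhere with 0.6 on the diagonal.
#' @param background_p Interaction probability for non-matched group pairs
#'   (used to build the default `affinity`).
#' @param seed Optional integer seed; the whole dataset is a deterministic
#'   function of it.
#' @return A list of class `lmi_simulation`: `lnc_expr` and `mi_expr`
#'   (expression matrices), `interactions` (binary lncRNA x miRNA matrix),
#'   `lnc_groups`, `mi_groups` (integer label vectors), and `config`.
#' @export
simulate_lmi_data <- function(n_lnc = 120, n_mi = 40, n_conditions = 24,
                              n_groups = 4, noise_sd = 0.3, affinity = NULL,
                              background_p = 0.02, seed = NULL) {
  if (n_conditions < 3) stop_spmlmi("'n_conditions' must be >= 3")
  if (noise_sd < 0) stop_spmlmi("'noise_sd' must be >= 0")
  if (is.null(affinity))
    affinity <- default_affinity(n_groups, background_p = background_p)
  if (!is.matrix(affinity) || any(dim(affinity) != n_groups))
    stop_spmlmi(sprintf("'affinity' must be %d x %d", n_groups, n_groups))
  if (any(affinity < 0 | affinity > 1) || background_p < 0 || background_p > 1)
    stop_spmlmi("probabilities must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  lnc_groups <- group_labels(n_lnc, n_groups)
  mi_groups <- group_labels(n_mi, n_groups)

  make_expr <- function(n, groups, prefix) {
    signal <- matrix(stats::rnorm(n_groups * n_conditions), n_groups)
    x <- signal[groups, , drop = FALSE] +
      noise_sd * matrix(stats::rnorm(n * n_conditions), n)
    dimnames(x) <- list(sprintf("%s%04d", prefix, seq_len(n)),
                        sprintf("cond%02d", seq_len(n_conditions)))
    x
  }
  lnc_expr <- make_expr(n_lnc, lnc_groups, "LNC")
  mi_expr <- make_expr(n_mi, mi_groups, "MIR")

  p <- affinity[cbind(rep(lnc_groups, times = n_mi),
                      rep(mi_groups, each = n_lnc))]
  lm <- matrix(as.numeric(stats::runif(n_lnc * n_mi) < p), n_lnc, n_mi,
               dimnames = list(rownames(lnc_expr), rownames(mi_expr)))

  structure(list(lnc_expr = lnc_expr, mi_expr = mi_expr, interactions = lm,
                 lnc_groups = lnc_groups, mi_groups = mi_groups,
                 config = list(n_lnc = n_lnc, n_mi = n_mi,
                               n_conditions = n_conditions,
                               n_groups = n_groups, noise_sd = noise_sd,
                               affinity = affinity,
                               background_p = background_p, seed = seed)),
            class = "lmi_simulation")
}

#' @export
print.lmi_simulation <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Synthetic lncRNA-miRNA dataset: %d lncRNAs x %d miRNAs, %d conditions\n",
              cfg$n_lnc, cfg$n_mi, cfg$n_conditions))
  cat(sprintf("  %d groups, noise sd %.2g, %d interactions (density %.3f, expected %.3f)\n",
              cfg$n_groups, cfg$noise_sd, sum(x$interactions),
              mean(x$interactions),
              expected_density(cfg$n_lnc, cfg$n_mi, cfg$n_groups,
                               cfg$affinity)))
  invisible(x)
}

#' Analytic expected interaction density
#'
#' Expected fraction of 1-entries in the simulated interaction matrix given
#' the (deterministic, even) group assignment and the affinity matrix.
#'
#' @inheritParams simulate_lmi_data
#' @return Scalar expected density in \[0, 1\].
#' @export
expected_density <- function(n_lnc = 120, n_mi = 40, n_groups = 4,
                             affinity = NULL, background_p = 0.02) {
  if (is.null(affinity))
    affinity <- default_affinity(n_groups, background_p = background_p)
  if (!is.matrix(affinity) || any(dim(affinity) != n_groups))
    stop_spmlmi(sprintf("'affinity' must be %d x %d", n_groups, n_groups))
  s <- tabulate(group_labels(n_lnc, n_groups), n_groups)
  u <- tabulate(group_labels(n_mi, n_groups), n_groups)
  as.numeric(s %*% affinity %*% u) / (n_lnc * n_mi)
}
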