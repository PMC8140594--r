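# The known-interaction layer and the bilayer block adjacency matrix.

#' Read a known lncRNA-miRNA interaction edge list
#'
#' Reads a two-column delimited file (lncRNA ID, miRNA ID). A header row is
#' detected when the first line carries common column labels ("lncRNA",
#' "miRNA", "id", "source", "target", ...). Duplicate pairs are collapsed; axis
#' orders follow first appearance in the file.
#'
#' @param path Path to the edge list. Delimiter inferred from the extension
#'   unless `sep` is given.
#' @param sep Optional field delimiter.
#' @return A binary matrix (lncRNAs x miRNAs) with identifier dimnames; an
#'   entry is 1 when the pair occurs in the file.
#' @export
read_interactions <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_spmlmi(sprintf("file not found: %s", path))
  sep <- detect_sep(path, sep)
  if (length(readLines(path, n = 1L)) == 0L)
    stop_spmlmi("empty interaction file")
  df <- utils::read.table(path, header = FALSE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "")
  if (nrow(df) == 0L) stop_spmlmi("empty interaction file")
  if (ncol(df) < 2L) stop_spmlmi("interaction file must have 2 columns")
  header_labels <- c("lncrna", "lnc", "lnc_id", "lncrna_id", "id", "source",
                     "mirna", "mi", "mi_id", "mirna_id", "target")
  first <- tolower(trimws(as.character(df[1L, 1:2])))
  if (any(first %in% header_labels)) df <- df[-1L, , drop = FALSE]
  if (nrow(df) == 0L) stop_spmlmi("empty interaction file")
  lnc <- as.character(df[[1L]])
  mi <- as.character(df[[2L]])
  if (any(lnc == mi))
    stop_spmlmi(sprintf("self-pair in interaction file: '%s'",
                        lnc[which(lnc == mi)[1L]]))
  dup <- duplicated(paste(lnc, mi, sep = "\r"))
  lnc <- lnc[!dup]
  mi <- mi[!dup]
  lnc_ids <- unique(lnc)
  mi_ids <- unique(mi)
  m <- matrix(0, length(lnc_ids), length(mi_ids),
              dimnames = list(lnc_ids, mi_ids))
  m[cbind(match(lnc, lnc_ids), match(mi, mi_ids))] <- 1
  m
}

#' Assemble the lncRNA-miRNA bilayer network
#'
#' Builds the block adjacency matrix
#' \deqn{A = \begin{bmatrix} LS & LM \\ LM^T & MS \end{bmatrix}}
#' where `LS`/`MS` are the lncRNA and miRNA similarity layers and `LM` the
#' binary interaction layer. lncRNA nodes come first, then miRNA nodes.
#'
#' @param ls Symmetric lncRNA similarity matrix (rownames = lncRNA IDs).
#' @param ms Symmetric miRNA similarity matrix (rownames = miRNA IDs).
#' @param lm Binary interaction matrix (lncRNAs x miRNAs) aligned with `ls`
#'   rows and `ms` rows in the same order.
#' @param lm_weight Scalar weight applied to interaction links (default 1;
#'   hook for scale-sensitivity experiments, the similarity blocks being
#'   real-valued while the interaction block is binary).
#' @return An object of class `bilayer_network`: a list with the N x N
#'   adjacency `A` (N = n_lnc + n_mi), counts `n_lnc`/`n_mi`, identifier
#'   vectors `lnc_ids`/`mi_ids`/`node_ids`, and `lm` (the weighted
#'   interaction block).
#' @export
bilayer_network <- function(ls, ms, lm, lm_weight = 1) {
  check_symmetric(ls, "ls")
  check_symmetric(ms, "ms")
  if (!is.matrix(lm) || !is.numeric(lm))
    stop_spmlmi("'lm' must be a numeric matrix")
  if (!all(lm %in% c(0, 1)))
    stop_spmlmi("'lm' entries must be 0 or 1")
  n_lnc <- nrow(lm)
  n_mi <- ncol(lm)
  if (nrow(ls) != n_lnc || nrow(ms) != n_mi)
    stop_spmlmi("similarity and interaction dimensions disagree")
  lnc_ids <- rownames(lm)
  mi_ids <- colnames(lm)
  if (!is.null(lnc_ids) && !is.null(rownames(ls))) {
    off <- which(rownames(ls) != lnc_ids)
    if (length(off))
      stop_spmlmi(sprintf("unaligned networks: lncRNA '%s' (position %d) differs between ls and lm",
                          rownames(ls)[off[1L]], off[1L]))
  }
  if (!is.null(mi_ids) && !is.null(rownames(ms))) {
    off <- which(rownames(ms) != mi_ids)
    if (length(off))
      stop_spmlmi(sprintf("unaligned networks: miRNA '%s' (position %d) differs between ms and lm",
                          rownames(ms)[off[1L]], off[1L]))
  }
  if (is.null(lnc_ids)) lnc_ids <- paste0("lnc", seq_len(n_lnc))
  if (is.null(mi_ids)) mi_ids <- paste0("mi", seq_len(n_mi))
  lmw <- lm * lm_weight
  a <- rbind(cbind(ls, lmw), cbind(t(lmw), ms))
  diag(a) <- 0
  node_ids <- c(lnc_ids, mi_ids)
  dimnames(a) <- list(node_ids, node_ids)
  structure(list(A = a, n_lnc = n_lnc, n_mi = n_mi,
                 lnc_ids = lnc_ids, mi_ids = mi_ids, node_ids = node_ids,
                 lm = lmw),
            class = "bilayer_network")
}

#' @export
print.bilayer_network <- function(x, ...) {
  cat(sprintf("lncRNA-miRNA bilayer network: %d nodes (%d lncRNAs + %d miRNAs)\n",
              x$n_lnc + x$n_mi, x$n_lnc, x$n_mi))
  cat(sprintf("  interaction links: %d   similarity links: %d (lnc) + %d (mi)\n",
              sum(x$lm != 0),
              sum(x$A[seq_len(x$n_lnc), seq_len(x$n_lnc)] != 0) / 2,
              sum(x$A[-seq_len(x$n_lnc), -seq_len(x$n_lnc)] != 0) / 2))
  invisible(x)
}

#' Extract the interaction block of a node-by-node matrix
#'
#' Returns the upper-right (lncRNA x miRNA) block of any N x N matrix that
#' is aligned with a bilayer network — typically the score matrix of a fit,
#' whose interaction block ranks candidate lncRNA-miRNA links.
#'
#' @param bn A `bilayer_network`.
#' @param scores An N x N matrix aligned with `bn` (default `bn$A`, whose
#'   block is the interaction layer itself).
#' @return An `n_lnc` x `n_mi` matrix with lncRNA/miRNA dimnames.
#' @export
interaction_block <- function(bn, scores = bn$A) {
  if (!inherits(bn, "bilayer_network")) stop_spmlmi("'bn' must be a bilayer_network")
  n <- bn$n_lnc + bn$n_mi
  if (!is_square(scores) || nrow(scores) != n)
    stop_spmlmi(sprintf("'scores' must be %d x %d", n, n))
  out <- scores[seq_len(bn$n_lnc), bn$n_lnc + seq_len(bn$n_mi), drop = FALSE]
  dimnames(out) <- list(bn$lnc_ids, bn$mi_ids)
  out
}
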