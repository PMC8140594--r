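# Expression profiles and expression-similarity networks.
#
# Expression matrices are plain numeric matrices: rows are RNAs (rownames =
# RNA identifiers), columns are tissues / cell lines (colnames = condition
# labels). Similarity networks are symmetric numeric matrices with zero
# diagonal and matching row/column names.

#' Read an expression-profile matrix
#'
#' Reads a delimited text file whose header row holds condition (tissue /
#' cell-line) labels and whose first column holds RNA identifiers. Rows with
#' any missing value are dropped, duplicate identifiers are collapsed to
#' their first occurrence with a warning, and an optional identifier filter
#' is applied while preserving file order.
#'
#' @param path Path to a delimited text file. The delimiter is inferred from
#'   the extension (`.csv` gives comma, anything else tab) unless `sep` is
#'   given.
#' @param id_filter Optional character vector of RNA identifiers to retain.
#' @param sep Optional field delimiter overriding the extension-based guess.
#' @return A numeric matrix (RNAs x conditions) with identifier rownames and
#'   condition colnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tbrain\tliver\tlung",
#'              "L1\t1\t2\t3",
#'              "L2\t0.5\t0.1\t0.9"), tf)
#' read_expression(tf)
#' @export
read_expression <- function(path, id_filter = NULL, sep = NULL) {
  if (!file.exists(path)) stop_spmlmi(sprintf("file not found: %s", path))
  sep <- detect_sep(path, sep)
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  nf <- nf[!is.na(nf)]
  if (length(nf) < 2L) stop_spmlmi(sprintf("'%s' has no data rows", path))
  bad <- which(nf != nf[1L])
  if (length(bad))
    stop_spmlmi(sprintf("parse error in '%s': line %d has %d fields, expected %d",
                        path, bad[1L], nf[bad[1L]], nf[1L]))
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), comment.char = "")
  if (ncol(df) < 3L)
    stop_spmlmi("expression matrix needs at least 2 conditions")
  ids <- as.character(df[[1L]])
  x <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(x) <- "double"

  keep <- stats::complete.cases(x)
  if (any(!keep)) {
    message(sprintf("dropped %d row(s) with missing values", sum(!keep)))
    x <- x[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  dup <- duplicated(ids)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate identifier(s) to first occurrence",
                    sum(dup)), call. = FALSE)
    x <- x[!dup, , drop = FALSE]
    ids <- ids[!dup]
  }
  if (!is.null(id_filter)) {
    keep <- ids %in% id_filter
    x <- x[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  if (nrow(x) == 0L) stop_spmlmi("no usable profiles after filtering")
  rownames(x) <- ids
  x
}

#' Standardize expression profiles
#'
#' Transforms each row (RNA) to mean 0 and standard deviation 1 across
#' conditions, using the population (1/n) standard deviation. Rows with zero
#' variance carry no correlation information and are removed with a warning.
#' The transform is idempotent.
#'
#' @param x Numeric matrix, RNAs in rows, conditions in columns.
#' @return The row-standardized matrix, possibly with fewer rows.
#' @export
standardize_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_spmlmi("'x' must be a numeric matrix")
  if (ncol(x) < 2L) stop_spmlmi("need at least 2 conditions")
  mu <- rowMeans(x)
  sdev <- sqrt(rowMeans((x - mu)^2))
  zero <- sdev == 0 | !is.finite(sdev)
  if (all(zero)) stop_spmlmi("degenerate expression matrix: all rows have zero variance")
  if (any(zero)) {
    warning(sprintf("removed %d zero-variance row(s): %s", sum(zero),
                    paste(utils::head(rownames(x)[zero], 5L), collapse = ", ")),
            call. = FALSE)
    x <- x[!zero, , drop = FALSE]
    mu <- mu[!zero]
    sdev <- sdev[!zero]
  }
  (x - mu) / sdev
}

#' Pearson expression-similarity network
#'
#' Pairwise Pearson correlation between RNA expression profiles. The
#' diagonal is set to 0 (no self-links): the downstream perturbation method
#' operates on link structure and self-similarity adds no information.
#' Negative correlations are kept as signed weights by default.
#'
#' @param x Numeric expression matrix (rows = RNAs); run
#'   [standardize_expression()] first so zero-variance rows are gone.
#' @param clip_negative If `TRUE`, negative correlations are set to 0
#'   (sensitivity-analysis hook; default keeps signed weights).
#' @return Symmetric numeric matrix of correlations with zero diagonal.
#' @export
expression_similarity <- function(x, clip_negative = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_spmlmi("'x' must be a numeric matrix")
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop_spmlmi("need at least 2 RNAs and 2 conditions")
  sdev <- apply(x, 1L, stats::sd)
  if (any(sdev == 0 | !is.finite(sdev)))
    stop_spmlmi("zero-variance row present; run standardize_expression() first")
  s <- stats::cor(t(x))
  s <- (s + t(s)) / 2          # exact symmetry regardless of fp noise
  diag(s) <- 0
  if (clip_negative) s[s < 0] <- 0
  s
}

#' Sparsify a dense similarity network
#'
#' Keeps the strongest `q` percent of off-diagonal entries by absolute
#' weight and zeroes the rest. A dense correlation network has no non-links,
#' so the structural-consistency index is undefined on it; sparsification
#' defines a link set first.
#'
#' @param s Symmetric similarity matrix.
#' @param q Percentage (0 < q <= 100) of strongest entries to keep.
#' @return The sparsified symmetric matrix.
#' @export
sparsify_similarity <- function(s, q = 10) {
  check_symmetric(s, "s")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 100)
    stop_spmlmi("'q' must be in (0, 100]")
  w <- abs(s[upper.tri(s)])
  n_keep <- max(1L, round(length(w) * q / 100))
  thr <- sort(w, decreasing = TRUE)[n_keep]
  out <- s
  out[abs(out) < thr] <- 0
  diag(out) <- 0
  out
}
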