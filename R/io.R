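# Plain-text (TSV) writers and readers for the pipeline's artifacts.

#' Write an expression or similarity matrix as TSV
#'
#' Dense tab-separated output with a header row of column labels and a
#' leading `id` column of row identifiers; the format [read_expression()]
#' reads back.
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an interaction matrix as a two-column edge list
#'
#' @param lm Binary lncRNA x miRNA matrix with dimnames.
#' @param path Output path.
#' @export
write_interactions <- function(lm, path) {
  idx <- which(lm != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  df <- data.frame(lncRNA = rownames(lm)[idx[, 1L]],
                   miRNA = colnames(lm)[idx[, 2L]],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a bilayer network as TSV
#'
#' `write_bilayer()` writes `<prefix>_A.tsv` (the dense adjacency with node
#' identifiers) and `<prefix>_meta.tsv` (layer bookkeeping: `n_lnc`,
#' `n_mi`); `read_bilayer()` reconstructs the `bilayer_network` from the
#' pair.
#'
#' @param bn A `bilayer_network`.
#' @param prefix Path prefix for the two files.
#' @return `write_bilayer()` the prefix, invisibly; `read_bilayer()` a
#'   `bilayer_network`.
#' @export
write_bilayer <- function(bn, prefix) {
  if (!inherits(bn, "bilayer_network")) stop_spmlmi("'bn' must be a bilayer_network")
  write_matrix_tsv(bn$A, paste0(prefix, "_A.tsv"))
  utils::write.table(data.frame(key = c("n_lnc", "n_mi"),
                                value = c(bn$n_lnc, bn$n_mi)),
                     paste0(prefix, "_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_bilayer
#' @export
read_bilayer <- function(prefix) {
  a_path <- paste0(prefix, "_A.tsv")
  meta_path <- paste0(prefix, "_meta.tsv")
  if (!file.exists(a_path) || !file.exists(meta_path))
    stop_spmlmi(sprintf("bilayer files '%s'/'%s' not found", a_path, meta_path))
  df <- utils::read.table(a_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  a <- as.matrix(df[, -1L, drop = FALSE])
  rownames(a) <- as.character(df[[1L]])
  storage.mode(a) <- "double"
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  n_lnc <- as.integer(meta$value[meta$key == "n_lnc"])
  n_mi <- as.integer(meta$value[meta$key == "n_mi"])
  li <- seq_len(n_lnc)
  mi <- n_lnc + seq_len(n_mi)
  bilayer_network(a[li, li, drop = FALSE], a[mi, mi, drop = FALSE],
                  a[li, mi, drop = FALSE])
}
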