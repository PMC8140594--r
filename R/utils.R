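# Internal helpers shared across the package.

#' @keywords internal
stop_spmlmi <- function(...) stop(..., call. = FALSE)

is_square <- function(x) is.matrix(x) && nrow(x) == ncol(x)

check_symmetric <- function(x, name = deparse(substitute(x)), tol = 1e-10) {
  if (!is_square(x) || !is.numeric(x))
    stop_spmlmi(sprintf("'%s' must be a square numeric matrix", name))
  if (max(abs(x - t(x))) > tol)
    stop_spmlmi(sprintf("'%s' must be symmetric", name))
  invisible(TRUE)
}

# Deterministic fan-out of independent child seeds from the current RNG
# state (or from `seed` when given). Kept below 2^31 so they are valid
# integer seeds.
child_seeds <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

# Upper-triangle (i < j) index pairs of nonzero entries of a symmetric
# matrix, as a 2-column integer matrix.
upper_pairs <- function(a, nonzero = TRUE) {
  idx <- which(upper.tri(a) & (if (nonzero) a != 0 else a == 0), arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx
}

# Auto-detect a field delimiter from a file extension (",", else tab).
detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}
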