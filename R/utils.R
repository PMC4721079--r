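#' @useDynLib riverpopgen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef resid fitted cor pnorm qnorm sd quantile setNames
#' @importFrom utils combn read.csv write.csv packageVersion
NULL

## Symmetric site-by-site matrix with a semantic label. Kept as a plain
## matrix subclass so linear algebra works unchanged.
pairwise_table <- function(mat, label, sites = rownames(mat)) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (is.null(sites)) sites <- paste0("S", seq_len(nrow(mat)))
  if (!isTRUE(all.equal(mat, t(mat), tolerance = 1e-12, check.attributes = FALSE)))
    stop("pairwise table must be symmetric")
  dimnames(mat) <- list(sites, sites)
  structure(mat, label = label, class = c("pairwise_table", "matrix", "array"))
}

#' Vectorize the lower triangle of a pairwise table
#'
#' Off-diagonal entries in a fixed (column-major lower-triangle) order, the
#' ordering shared by all matrix-correlation and regression code in the
#' package so that vectors from different tables align pair-by-pair.
#'
#' @param x square symmetric matrix
#' @return numeric vector of length n(n-1)/2
#' @export
offdiag <- function(x) x[lower.tri(x)]

## names of site pairs in offdiag() order
pair_labels <- function(sites) {
  n <- length(sites)
  idx <- which(lower.tri(diag(n)), arr.ind = TRUE)
  paste(sites[idx[, 2]], sites[idx[, 1]], sep = "-")
}

check_same_sites <- function(...) {
  mats <- list(...)
  ref <- rownames(mats[[1]])
  for (m in mats[-1]) {
    if (!identical(rownames(m), ref))
      stop("pairwise tables must share the same site order")
  }
  invisible(ref)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
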