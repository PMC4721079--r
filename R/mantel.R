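## Mantel and partial Mantel tests on pairwise matrices. Significance is by
## permutation of site labels; the partial test follows the
## Smouse-Long-Sokal scheme (permute the residualized response matrix).

mantel_result <- function(R, p, n_perm, conditioned_on = NA_character_) {
  structure(list(R = R, p = p, n_perm = n_perm,
                 conditioned_on = conditioned_on),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cond <- if (is.na(x$conditioned_on)) "" else
    paste0(" | ", x$conditioned_on)
  cat(sprintf("Mantel R%s = %.3f, p = %.4g (%d permutations)\n",
              cond, x$R, x$p, x$n_perm))
  invisible(x)
}

#' Mantel test between two pairwise tables
#'
#' Pearson correlation of the off-diagonal vectorizations, with a
#' permutation p-value obtained by simultaneously permuting rows and
#' columns of \code{X}. Default is one-sided for positive association (the
#' isolation-by-distance alternative),
#' \eqn{p = (1 + \#\{R^* \ge R\})/(n_{perm}+1)}.
#'
#' @param Y,X symmetric matrices over the same site order
#' @param n_perm number of permutations
#' @param alternative \code{"greater"} (default) or \code{"two.sided"}
#' @return \code{mantel_result} with fields \code{R}, \code{p}, \code{n_perm}
#' @export
mantel_test <- function(Y, X, n_perm = 10000, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  check_same_sites(Y, X)
  y <- offdiag(Y); x <- offdiag(X)
  if (sd(y) == 0 || sd(x) == 0) stop("constant matrix: Mantel R undefined")
  R <- cor(y, x)
  n <- nrow(Y)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(n)
    Rs <- cor(y, offdiag(X[perm, perm]))
    hit <- if (alternative == "greater") Rs >= R else abs(Rs) >= abs(R)
    if (hit) exceed <- exceed + 1L
  }
  mantel_result(R, (1 + exceed) / (n_perm + 1), n_perm)
}

#' Partial Mantel test
#'
#' Correlation between the residuals of \code{Y} on \code{Z} and of
#' \code{X} on \code{Z} (off-diagonal regressions). The permutation null
#' rebuilds the residualized response as a symmetric matrix and permutes its
#' site labels before re-correlating with the residualized predictor.
#'
#' @param Y response pairwise table
#' @param X predictor pairwise table
#' @param Z conditioning pairwise table
#' @inheritParams mantel_test
#' @return \code{mantel_result} with \code{conditioned_on} set
#' @export
partial_mantel <- function(Y, X, Z, n_perm = 10000,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  check_same_sites(Y, X, Z)
  y <- offdiag(Y); x <- offdiag(X); z <- offdiag(Z)
  if (sd(x) == 0 || sd(z) == 0) stop("constant matrix")
  if (abs(cor(x, z)) >= 1 - 1e-12)
    stop("predictor and conditioning matrices are perfectly collinear")
  ry <- resid(lm(y ~ z))
  rx <- resid(lm(x ~ z))
  R <- cor(ry, rx)
  n <- nrow(Y)
  RY <- matrix(0, n, n)
  RY[lower.tri(RY)] <- ry
  RY <- RY + t(RY)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(n)
    Rs <- cor(offdiag(RY[perm, perm]), rx)
    hit <- if (alternative == "greater") Rs >= R else abs(Rs) >= abs(R)
    if (hit) exceed <- exceed + 1L
  }
  mantel_result(R, (1 + exceed) / (n_perm + 1), n_perm,
                conditioned_on = attr(Z, "label") %||% "Z")
}
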