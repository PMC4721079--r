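## Effective population size from linkage disequilibrium among unlinked
## loci: Burrows composite disequilibrium, sample-size bias correction for
## random mating, and a jackknife over locus pairs for confidence intervals.

## dosage matrix for one locus: individuals x alleles, entries 0/1/2 copies,
## NA rows for missing genotypes; columns restricted to alleles with
## pcrit < frequency < 1
dosage_screened <- function(amat, pcrit) {
  ok <- !is.na(amat[, 1])
  if (sum(ok) == 0) return(NULL)
  cnt <- allele_counts(amat)
  p <- cnt / sum(cnt)
  keep <- names(cnt)[p > pcrit & p < 1]
  if (!length(keep)) return(NULL)
  X <- matrix(NA_real_, nrow(amat), length(keep),
              dimnames = list(NULL, keep))
  for (k in seq_along(keep)) {
    A <- as.integer(keep[k])
    X[ok, k] <- (amat[ok, 1] == A) + (amat[ok, 2] == A)
  }
  X
}

## mean squared Burrows correlation for one locus pair.
## X, Y: dosage matrices; returns list(r2, S) or NULL if uninformative.
burrows_r2_pair <- function(X, Y) {
  ok <- !is.na(X[, 1]) & !is.na(Y[, 1])
  S <- sum(ok)
  if (S < 3) return(NULL)
  X <- X[ok, , drop = FALSE]; Y <- Y[ok, , drop = FALSE]
  r2 <- c()
  for (a in seq_len(ncol(X))) for (b in seq_len(ncol(Y))) {
    x <- X[, a]; y <- Y[, b]
    pA <- mean(x) / 2; pB <- mean(y) / 2
    if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) next
    delta <- (S / (S - 1)) * (mean(x * y) / 2 - 2 * pA * pB)
    dA <- pA * (1 - pA) + (mean(x == 2) - pA^2)
    dB <- pB * (1 - pB) + (mean(y == 2) - pB^2)
    if (dA <= 0 || dB <= 0) next
    r2 <- c(r2, delta^2 / (dA * dB))
  }
  if (!length(r2)) return(NULL)
  list(r2 = mean(r2), S = S, n_comp = length(r2))
}

## expected r^2 from sampling alone under random mating (Waples 2006)
expected_r2 <- function(S) {
  ifelse(S >= 30, 1 / S + 3.19 / S^2, 0.0018 + 0.907 / S + 4.44 / S^2)
}

## invert E[r2_drift] ~ f(Ne) for the random-mating model
ne_from_r2drift <- function(r2d, S) {
  if (is.na(r2d) || r2d <= 0) return(Inf)
  if (S >= 30) (1 / 3 + sqrt(max(0, 1 / 9 - 2.76 * r2d))) / (2 * r2d)
  else (0.308 + sqrt(max(0, 0.308^2 - 2.08 * r2d))) / (2 * r2d)
}

#' LD effective population size for one site
#'
#' Computes Burrows' composite disequilibrium for every allele pair across
#' every pair of loci (alleles screened to frequency strictly above
#' \code{pcrit}), averages the squared correlations weighted by the pair
#' sample size, subtracts the random-mating sampling expectation
#' \eqn{E[r^2|S]} (\eqn{1/S + 3.19/S^2} for \eqn{S \ge 30}), and maps the
#' drift residual to \eqn{\hat N_e}. Non-positive residuals give an infinite
#' estimate (no drift signal). Confidence intervals come from a jackknife
#' over locus pairs on the adjusted \eqn{r^2} scale.
#'
#' @param ds genotype_dataset
#' @param site site id
#' @param pcrit allele-frequency screening threshold (alleles at frequency
#'   exactly \code{pcrit} are excluded)
#' @param conf confidence level for the jackknife interval
#' @return object of class \code{ne_estimate}: list with \code{site},
#'   \code{ne}, \code{ci_low}, \code{ci_high} (\code{Inf} allowed),
#'   \code{n_pairs}, \code{pcrit}, \code{r2}, \code{r2_expected},
#'   \code{r2_drift}, \code{S}
#' @export
ld_ne <- function(ds, site, pcrit = 0.02, conf = 0.95) {
  rows <- site_index(ds, site)
  dos <- lapply(ds$loci, function(l)
    dosage_screened(locus_alleles(ds, l, rows), pcrit))
  dos <- Filter(Negate(is.null), dos)
  if (length(dos) < 2)
    stop("site ", site, ": fewer than 2 polymorphic loci after screening")
  prs <- combn(length(dos), 2)
  stats <- lapply(seq_len(ncol(prs)), function(j)
    burrows_r2_pair(dos[[prs[1, j]]], dos[[prs[2, j]]]))
  stats <- Filter(Negate(is.null), stats)
  if (!length(stats)) stop("site ", site, ": no informative locus pairs")
  r2 <- vapply(stats, `[[`, 0, "r2")
  S <- vapply(stats, `[[`, 0, "S")
  wsum <- function(idx) {
    w <- S[idx]
    c(r2 = sum(w * r2[idx]) / sum(w),
      e = sum(w * expected_r2(S[idx])) / sum(w),
      S = sum(w * S[idx]) / sum(w))
  }
  full <- wsum(seq_along(r2))
  r2d <- full["r2"] - full["e"]
  ne <- ne_from_r2drift(r2d, full["S"])
  J <- length(r2)
  ci <- c(NA_real_, NA_real_)
  if (J >= 2) {
    jk <- vapply(seq_len(J), function(j) {
      w <- wsum(setdiff(seq_len(J), j)); w["r2"] - w["e"]
    }, 0)
    se <- sqrt((J - 1) / J * sum((jk - mean(jk))^2))
    z <- qnorm(1 - (1 - conf) / 2)
    ci_r2 <- c(r2d - z * se, r2d + z * se)
    ci <- c(ne_from_r2drift(ci_r2[2], full["S"]),
            ne_from_r2drift(ci_r2[1], full["S"]))
  }
  structure(list(site = site, ne = unname(ne), ci_low = unname(ci[1]),
                 ci_high = unname(ci[2]), n_pairs = J, pcrit = pcrit,
                 r2 = unname(full["r2"]), r2_expected = unname(full["e"]),
                 r2_drift = unname(r2d), S = unname(full["S"])),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  fmt <- function(v) if (is.infinite(v)) "inf" else sprintf("%.0f", v)
  cat(sprintf("LD-Ne at %s: %s (%s-%s), %d locus pairs, Pcrit=%g\n",
              x$site, fmt(x$ne), fmt(x$ci_low), fmt(x$ci_high),
              x$n_pairs, x$pcrit))
  invisible(x)
}

#' LD-Ne for every site
#' @inheritParams ld_ne
#' @return data.frame \code{site, Ne, ci_low, ci_high, n_pairs} (infinite
#'   values serialized as \code{Inf})
#' @export
ld_ne_sites <- function(ds, pcrit = 0.02, conf = 0.95) {
  do.call(rbind, lapply(site_ids(ds), function(s) {
    e <- tryCatch(ld_ne(ds, s, pcrit, conf), error = function(err) NULL)
    if (is.null(e))
      return(data.frame(site = s, Ne = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, n_pairs = 0L))
    data.frame(site = s, Ne = e$ne, ci_low = e$ci_low, ci_high = e$ci_high,
               n_pairs = e$n_pairs)
  }))
}
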