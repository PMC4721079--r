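## Per-site diversity: observed/expected heterozygosity, Weir-Cockerham
## F_IS with a within-site allele-permutation test, and allelic richness by
## hypergeometric rarefaction.

## allele counts (copies) at one locus for a set of rows; named integer vector
allele_counts <- function(amat) {
  a <- c(amat[, 1], amat[, 2])
  a <- a[!is.na(a)]
  if (!length(a)) return(integer(0))
  tab <- table(a)
  setNames(as.integer(tab), names(tab))
}

#' Unbiased expected heterozygosity at one locus
#'
#' Nei's unbiased gene diversity \eqn{\frac{2n}{2n-1}(1 - \sum_k p_k^2)} with
#' \eqn{n} the number of non-missing diploid genotypes.
#'
#' @param amat two-column matrix of allele pairs (rows = individuals,
#'   \code{NA} = missing), as stored in a \code{genotype_dataset}
#' @return gene diversity in \[0, 1\], or \code{NA} if all genotypes missing
#' @export
expected_heterozygosity <- function(amat) {
  ok <- !is.na(amat[, 1])
  n <- sum(ok)
  if (n == 0) return(NA_real_)
  cnt <- allele_counts(amat)
  p <- cnt / (2 * n)
  if (n == 1) return(NA_real_)            # unbiased estimator needs 2n-1 > 1
  (2 * n / (2 * n - 1)) * (1 - sum(p^2))
}

#' Observed heterozygosity at one locus
#' @inheritParams expected_heterozygosity
#' @return proportion of heterozygous genotypes among non-missing ones
#' @export
observed_heterozygosity <- function(amat) {
  ok <- !is.na(amat[, 1])
  if (!sum(ok)) return(NA_real_)
  mean(amat[ok, 1] != amat[ok, 2])
}

## Weir-Cockerham within-population variance components for one locus in a
## single sample: for each allele A, with n non-missing diploids, p its
## frequency and h the proportion of individuals heterozygous for A,
##   b = n/(n-1) * (p(1-p) - (2n-1)/(4n) h),   c = h/2.
## f = 1 - sum(c)/sum(b+c) accumulated over alleles (and loci).
fis_components <- function(amat) {
  ok <- !is.na(amat[, 1])
  n <- sum(ok)
  if (n < 2) return(NULL)
  a1 <- amat[ok, 1]; a2 <- amat[ok, 2]
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2) return(NULL)   # monomorphic: no information
  p <- (colSums(outer(a1, alleles, "==")) +
        colSums(outer(a2, alleles, "=="))) / (2 * n)
  het <- a1 != a2
  h <- vapply(alleles, function(A) mean(het & (a1 == A | a2 == A)), 0)
  b <- (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
  cbind(b = b, c = h / 2)
}

#' Within-site inbreeding coefficient (Weir-Cockerham f)
#'
#' Multilocus f as a ratio of summed variance components,
#' \eqn{f = 1 - \sum c / \sum (b + c)}, with the sums running over alleles
#' and loci. An optional permutation test randomizes alleles among
#' individuals within the site (per locus, preserving missingness) and
#' reports the two-sided p-value \eqn{(1 + \#\{|f^*| \ge |f|\})/(n_{perm}+1)}.
#'
#' @param ds genotype_dataset
#' @param site site id
#' @param n_perm number of within-site allele permutations (0 = no test)
#' @return list with \code{fis}, and \code{p} if \code{n_perm > 0};
#'   \code{fis} is \code{NA} if no locus is polymorphic at the site
#' @export
fis <- function(ds, site, n_perm = 0) {
  rows <- site_index(ds, site)
  if (length(rows) < 2) stop("need >= 2 individuals at site ", site)
  mats <- lapply(ds$loci, function(l) locus_alleles(ds, l, rows))
  f_of <- function(ms) {
    comp <- do.call(rbind, lapply(ms, fis_components))
    if (is.null(comp) || sum(comp[, "b"] + comp[, "c"]) <= 0) return(NA_real_)
    1 - sum(comp[, "c"]) / sum(comp[, "b"] + comp[, "c"])
  }
  f <- f_of(mats)
  out <- list(site = site, fis = f)
  if (n_perm > 0 && !is.na(f)) {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      perm <- lapply(mats, function(m) {
        ok <- !is.na(m[, 1])
        pool <- sample(c(m[ok, 1], m[ok, 2]))
        m[ok, ] <- matrix(pool, ncol = 2)
        m
      })
      fstar <- f_of(perm)
      if (!is.na(fstar) && abs(fstar) >= abs(f)) exceed <- exceed + 1L
    }
    out$p <- (1 + exceed) / (n_perm + 1)
  }
  out
}

#' Allelic richness by rarefaction at one locus
#'
#' Expected number of distinct alleles in a random subsample of \code{g}
#' diploids (\code{2g} gene copies) drawn without replacement:
#' \eqn{AR = \sum_k [1 - C(2n - N_k, 2g)/C(2n, 2g)]} with \eqn{N_k} copies of
#' allele k among the \eqn{2n} sampled copies (hypergeometric rarefaction).
#'
#' @inheritParams expected_heterozygosity
#' @param g rarefaction size in diploid individuals
#' @return expected allele count (\code{>= 1}), or \code{NA} with a warning
#'   if fewer than \code{g} non-missing genotypes are available
#' @export
allelic_richness <- function(amat, g) {
  ok <- !is.na(amat[, 1])
  n <- sum(ok)
  if (g < 1) stop("g must be >= 1")
  if (g > n) {
    warning("rarefaction size g exceeds available sample; locus skipped")
    return(NA_real_)
  }
  cnt <- allele_counts(amat)
  tot <- 2 * n
  sum(1 - exp(lchoose(tot - cnt, 2 * g) - lchoose(tot, 2 * g)))
}

## smallest per-locus non-missing diploid count over all sites and loci
min_locus_n <- function(ds) {
  mn <- Inf
  for (s in site_ids(ds)) {
    rows <- site_index(ds, s)
    nm <- colSums(!is.na(ds$alleles[rows, , 1, drop = FALSE]))
    mn <- min(mn, nm)
  }
  as.integer(mn)
}

#' Per-site diversity summary
#'
#' Sample size, multilocus observed and unbiased expected heterozygosity,
#' Weir-Cockerham F_IS, and allelic richness rarefied to \code{g} diploids.
#' Multilocus values are unweighted means over loci; F_IS is the
#' variance-component ratio over loci.
#'
#' @param ds genotype_dataset
#' @param g rarefaction size in diploids; default is the smallest per-locus
#'   non-missing sample size over all sites and loci
#' @param fis_perm permutations for the per-site F_IS test (0 = none)
#' @return data.frame with one row per site: \code{site, N, Ho, He, Fis, AR}
#'   (+ \code{Fis_p} if tested) and attribute \code{g}
#' @export
site_diversity <- function(ds, g = NULL, fis_perm = 0) {
  if (is.null(g)) g <- min_locus_n(ds)
  res <- lapply(site_ids(ds), function(s) {
    rows <- site_index(ds, s)
    ho <- he <- ar <- numeric(length(ds$loci))
    for (j in seq_along(ds$loci)) {
      m <- locus_alleles(ds, ds$loci[j], rows)
      ho[j] <- observed_heterozygosity(m)
      he[j] <- expected_heterozygosity(m)
      ar[j] <- suppressWarnings(allelic_richness(m, g))
    }
    f <- fis(ds, s, n_perm = fis_perm)
    row <- data.frame(site = s, N = length(rows),
                      Ho = mean(ho, na.rm = TRUE), He = mean(he, na.rm = TRUE),
                      Fis = f$fis, AR = mean(ar, na.rm = TRUE))
    if (fis_perm > 0) row$Fis_p <- f$p %||% NA_real_
    row
  })
  out <- do.call(rbind, res)
  attr(out, "g") <- g
  out
}

#' Single-locus Hardy-Weinberg tests across sites and loci
#'
#' For every site-locus combination, tests departure from Hardy-Weinberg
#' proportions by permuting alleles among individuals within the site and
#' comparing |f| of the permuted data to the observed |f| (two-sided).
#' Monomorphic site-locus combinations are reported with \code{NA}.
#'
#' @param ds genotype_dataset
#' @param n_perm permutations per test
#' @return data.frame \code{site, locus, fis, p}; attribute \code{n_tests}
#'   counts the informative (non-NA) tests performed
#' @export
hwe_scan <- function(ds, n_perm = 1000) {
  grid <- expand.grid(site = site_ids(ds), locus = ds$loci,
                      stringsAsFactors = FALSE)
  res <- mapply(function(s, l) {
    m <- locus_alleles(ds, l, site_index(ds, s))
    comp <- fis_components(m)
    if (is.null(comp)) return(c(NA_real_, NA_real_))
    f <- 1 - sum(comp[, "c"]) / sum(comp[, "b"] + comp[, "c"])
    exceed <- 0L
    ok <- !is.na(m[, 1])
    for (b in seq_len(n_perm)) {
      mp <- m
      mp[ok, ] <- matrix(sample(c(m[ok, 1], m[ok, 2])), ncol = 2)
      cp <- fis_components(mp)
      fstar <- if (is.null(cp)) NA_real_ else
        1 - sum(cp[, "c"]) / sum(cp[, "b"] + cp[, "c"])
      if (!is.na(fstar) && abs(fstar) >= abs(f)) exceed <- exceed + 1L
    }
    c(f, (1 + exceed) / (n_perm + 1))
  }, grid$site, grid$locus)
  out <- data.frame(grid, fis = res[1, ], p = res[2, ])
  attr(out, "n_tests") <- sum(!is.na(out$p))
  out
}
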