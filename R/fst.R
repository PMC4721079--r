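## Weir-Cockerham (1984) theta: variance components a (among populations),
## b (among individuals within populations) and c (within individuals),
## computed per allele per locus with unequal sample sizes and summed.

## components for one locus over r populations.
## mats: list of two-column allele matrices, one per population.
## Returns matrix with columns a, b, c (one row per allele) or NULL if the
## locus is uninformative (monomorphic pooled, or < 2 populations scored).
wc_locus_components <- function(mats) {
  ok <- lapply(mats, function(m) m[!is.na(m[, 1]), , drop = FALSE])
  ok <- ok[vapply(ok, nrow, 0L) > 0]
  r <- length(ok)
  if (r < 2) return(NULL)
  alleles <- sort(unique(unlist(lapply(ok, function(m) c(m[, 1], m[, 2])))))
  if (length(alleles) < 2) return(NULL)
  n <- vapply(ok, nrow, 0L)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  out <- matrix(0, nrow = length(alleles), ncol = 3,
                dimnames = list(alleles, c("a", "b", "c")))
  for (k in seq_along(alleles)) {
    A <- alleles[k]
    p <- vapply(ok, function(m) (sum(m[, 1] == A) + sum(m[, 2] == A)) / (2 * nrow(m)), 0)
    h <- vapply(ok, function(m) mean((m[, 1] == A) != (m[, 2] == A)), 0)
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    inner <- pbar * (1 - pbar) - (r - 1) / r * s2
    a <- (nbar / nc) * (s2 - (inner - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
    out[k, ] <- c(a, b, hbar / 2)
  }
  out
}

#' Weir-Cockerham theta over a set of sites
#'
#' Variance-components estimator of F_ST for unequal sample sizes:
#' per-allele components a, b, c are accumulated over alleles and loci and
#' combined as \eqn{\theta = \sum a / \sum(a+b+c)}. Negative estimates are
#' retained (no truncation). Loci monomorphic in the pooled subset carry no
#' information and are skipped; if all are, theta is \code{NA}.
#'
#' @param ds genotype_dataset
#' @param sites site ids to include (default all)
#' @param loci locus names to include (default all)
#' @return list: \code{theta}, per-locus \code{theta_by_locus}, and the
#'   per-locus component sums \code{components} (matrix loci x \{a, abc\})
#' @export
wc_theta <- function(ds, sites = site_ids(ds), loci = ds$loci) {
  if (length(sites) < 2) stop("need >= 2 sites")
  rows <- lapply(sites, function(s) site_index(ds, s))
  comp <- matrix(NA_real_, nrow = length(loci), ncol = 2,
                 dimnames = list(loci, c("a", "abc")))
  for (j in seq_along(loci)) {
    mats <- lapply(rows, function(rw) locus_alleles(ds, loci[j], rw))
    cl <- wc_locus_components(mats)
    if (!is.null(cl)) comp[j, ] <- c(sum(cl[, "a"]), sum(cl))
  }
  use <- !is.na(comp[, "abc"]) & comp[, "abc"] != 0
  theta <- if (any(use)) sum(comp[use, "a"]) / sum(comp[use, "abc"]) else NA_real_
  list(theta = theta,
       theta_by_locus = comp[, "a"] / comp[, "abc"],
       components = comp)
}

## Per-locus per-site sufficient statistics for pairwise theta:
## sample sizes, allele frequencies and per-allele heterozygote
## proportions, aligned on the locus's global allele list.
locus_summaries <- function(ds) {
  sts <- site_ids(ds)
  lapply(ds$loci, function(l) {
    full <- locus_alleles(ds, l)
    alleles <- sort(unique(c(full[, 1], full[, 2])))
    P <- H <- matrix(0, length(alleles), length(sts),
                     dimnames = list(alleles, sts))
    n <- setNames(integer(length(sts)), sts)
    for (s in sts) {
      m <- full[site_index(ds, s), , drop = FALSE]
      m <- m[!is.na(m[, 1]), , drop = FALSE]
      n[s] <- nrow(m)
      if (!nrow(m)) next
      X <- outer(m[, 1], alleles, "==") + outer(m[, 2], alleles, "==")
      P[, s] <- colSums(X) / (2 * nrow(m))
      H[, s] <- colMeans(X == 1)
    }
    list(alleles = alleles, n = n, P = P, H = H)
  })
}

## two-population theta components from precomputed summaries; returns the
## per-locus (a, abc) sums as in wc_theta()$components
pair_components <- function(summ, s1, s2) {
  nl <- length(summ)
  comp <- matrix(NA_real_, nl, 2, dimnames = list(NULL, c("a", "abc")))
  for (j in seq_len(nl)) {
    sm <- summ[[j]]
    n1 <- sm$n[[s1]]; n2 <- sm$n[[s2]]
    if (n1 == 0 || n2 == 0) next
    p1 <- sm$P[, s1]; p2 <- sm$P[, s2]
    nbar <- (n1 + n2) / 2
    pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
    keep <- pbar > 0 & pbar < 1
    if (!any(keep)) next
    p1 <- p1[keep]; p2 <- p2[keep]; pbar <- pbar[keep]
    h1 <- sm$H[keep, s1]; h2 <- sm$H[keep, s2]
    nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
    s2v <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
    hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
    inner <- pbar * (1 - pbar) - s2v / 2
    a <- (nbar / nc) * (s2v - (inner - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    comp[j, ] <- c(sum(a), sum(a + b + cc))
  }
  comp
}

theta_from_components <- function(comp) {
  use <- !is.na(comp[, "abc"]) & comp[, "abc"] != 0
  if (!any(use)) return(NA_real_)
  sum(comp[use, "a"]) / sum(comp[use, "abc"])
}

#' Pairwise Weir-Cockerham F_ST between all sites
#'
#' Point estimate per site pair, with optional uncertainty from
#' bootstrapping over loci (percentile interval; with few loci the interval
#' is coarse) and an optional permutation test that shuffles genotypes
#' between the two sites.
#'
#' @param ds genotype_dataset
#' @param n_boot bootstrap resamples over loci (0 = none)
#' @param n_perm permutations per pair for a p-value (0 = none)
#' @param conf confidence level for the percentile interval
#' @return \code{pairwise_table} labelled \code{"FST"}; if bootstrapped,
#'   attributes \code{ci_low}/\code{ci_high} hold matching matrices, and
#'   \code{p} holds permutation p-values if requested
#' @export
pairwise_fst <- function(ds, n_boot = 0, n_perm = 0, conf = 0.95) {
  sts <- site_ids(ds)
  ns <- length(sts)
  if (ns < 2) stop("need >= 2 sites")
  if (n_boot > 0 && length(ds$loci) < 2) {
    warning("fewer than 2 loci: bootstrap skipped, point estimates only")
    n_boot <- 0
  }
  summ <- locus_summaries(ds)
  fstm <- lo <- hi <- pm <- matrix(0, ns, ns, dimnames = list(sts, sts))
  alpha <- (1 - conf) / 2
  for (i in seq_len(ns - 1)) for (k in (i + 1):ns) {
    comp <- pair_components(summ, sts[i], sts[k])
    fstm[i, k] <- fstm[k, i] <- theta_from_components(comp)
    if (n_boot > 0) {
      use <- which(!is.na(comp[, "abc"]) & comp[, "abc"] != 0)
      bs <- replicate(n_boot, {
        idx <- sample(use, length(use), replace = TRUE)
        sum(comp[idx, "a"]) / sum(comp[idx, "abc"])
      })
      q <- quantile(bs, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
      lo[i, k] <- lo[k, i] <- q[1]
      hi[i, k] <- hi[k, i] <- q[2]
    }
    if (n_perm > 0) {
      sub <- subset_sites(ds, c(sts[i], sts[k]))
      obs <- fstm[i, k]
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        shuffled <- sub
        shuffled$ind$site <- sample(sub$ind$site)
        tstar <- wc_theta(shuffled)$theta
        if (!is.na(tstar) && tstar >= obs) exceed <- exceed + 1L
      }
      pm[i, k] <- pm[k, i] <- (1 + exceed) / (n_perm + 1)
    }
  }
  out <- pairwise_table(fstm, "FST", sts)
  if (n_boot > 0) { attr(out, "ci_low") <- lo; attr(out, "ci_high") <- hi }
  if (n_perm > 0) attr(out, "p") <- pm
  out
}
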