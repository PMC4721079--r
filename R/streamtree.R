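## Stream-tree model: least-squares assignment of genetic distance to river
## sections so that pairwise genetic distances are (approximately) the sums
## over the connecting path. Non-negative section distances by default,
## solved with an active-set NNLS; sections that always co-occur on paths
## are merged (individually unidentifiable), sections traversed by no pair
## are reported as unidentifiable.

#' Fit the stream-tree model of pairwise genetic distance
#'
#' Builds the path-incidence matrix A (site pairs x sections, 1 where the
#' section lies on the pair's path) and solves
#' \eqn{\min_d \|A d - f\|^2}, optionally subject to \eqn{d \ge 0}, where f
#' is the off-diagonal vector of the genetic-distance table (F_ST here,
#' negatives permitted). Fit quality is
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} on the pairwise vector.
#'
#' @param fst \code{pairwise_table} of genetic distances
#' @param net river_network (loop-flagged edges are never routed; sites on
#'   the loop should be excluded via \code{exclude_sites})
#' @param exclude_sites site ids to drop before fitting (e.g. sites whose
#'   routing would require a loop edge)
#' @param constrain_nonneg force section distances >= 0 (default TRUE)
#' @return object of class \code{streamtree_fit}: \code{$sections}
#'   (edge_id, d, group, identifiable), \code{$r2}, \code{$fitted},
#'   \code{$residuals} (pairwise matrices), \code{$excluded_sites},
#'   \code{$merge_map}
#' @export
fit_streamtree <- function(fst, net, exclude_sites = character(0),
                           constrain_nonneg = TRUE) {
  sites <- setdiff(rownames(fst), exclude_sites)
  if (length(sites) < 3) stop("need >= 3 sites after exclusions")
  f <- offdiag(fst[sites, sites])
  npair <- length(f)
  eids <- net$edges$edge_id
  A <- matrix(0L, npair, length(eids), dimnames = list(NULL, eids))
  row <- 0L
  n <- length(sites)
  for (k in seq_len(n - 1)) for (i in (k + 1):n) {
    ## offdiag() order: column-major lower triangle -> (i, k), i > k
    row <- row + 1L
    pe <- path_edge_ids(net, node_of_site(net, sites[k]),
                        node_of_site(net, sites[i]))
    A[row, match(pe, eids)] <- 1L
  }

  used <- colSums(A) > 0
  unidentifiable <- eids[!used]
  Ause <- A[, used, drop = FALSE]
  ## merge sections with identical incidence columns: only their sum is
  ## estimable, reported as one group
  sig <- apply(Ause, 2, paste, collapse = "")
  group <- match(sig, unique(sig))
  G <- matrix(0L, ncol(Ause), max(group))
  G[cbind(seq_along(group), group)] <- 1L
  Ag <- Ause %*% G                      # pairs x groups (0/1 by construction)

  d_group <- if (constrain_nonneg) {
    pracma::lsqnonneg(Ag, f)$x
  } else {
    qr.coef(qr(Ag), f)
  }
  fitted <- as.vector(Ag %*% d_group)
  ss_res <- sum((f - fitted)^2)
  ss_tot <- sum((f - mean(f))^2)

  sections <- data.frame(edge_id = eids,
                         d = NA_real_,
                         group = NA_integer_,
                         identifiable = used)
  sections$group[used] <- group
  sections$d[used] <- d_group[group]    # group total, shared by members
  merge_map <- split(colnames(Ause), group)
  names(merge_map) <- paste0("g", seq_along(merge_map))

  mkmat <- function(v) {
    M <- matrix(0, n, n, dimnames = list(sites, sites))
    M[lower.tri(M)] <- v
    M + t(M)
  }
  structure(list(sections = sections, r2 = 1 - ss_res / ss_tot,
                 d_group = d_group,
                 fitted = mkmat(fitted), residuals = mkmat(f - fitted),
                 excluded_sites = exclude_sites, merge_map = merge_map,
                 constrain_nonneg = constrain_nonneg),
            class = "streamtree_fit")
}

#' @export
print.streamtree_fit <- function(x, ...) {
  cat(sprintf("streamtree_fit: R2 = %.3f, %d sections (%d groups), %d unidentifiable\n",
              x$r2, nrow(x$sections), length(x$d_group),
              sum(!x$sections$identifiable)))
  nz <- sum(x$d_group <= 1e-12)
  cat(sprintf("  groups fitted at zero: %d of %d\n", nz, length(x$d_group)))
  if (length(x$excluded_sites))
    cat("  excluded sites:", paste(x$excluded_sites, collapse = ", "), "\n")
  invisible(x)
}
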