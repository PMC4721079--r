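## Candidate barrier regressions with AIC model selection, permutation
## p-values (Freedman-Lane), commonality analysis and virtual-distance
## conversion. For pairwise responses the effective sample size used in AIC
## is the number of populations, not the number of pairs, to compensate for
## the non-independence of pairwise data.

#' Least-squares AIC
#'
#' \eqn{AIC = n \ln(RSS/n) + 2k} with \code{k} the number of estimated mean
#' parameters (intercept + slopes). The Gaussian constant and the variance
#' parameter shift all candidate AICs equally and cancel in differences,
#' which are the only quantities interpreted.
#'
#' @param rss residual sum of squares
#' @param n effective sample size
#' @param k number of mean parameters (intercept + slopes)
#' @return AIC value
#' @export
aic_ls <- function(rss, n, k) n * log(rss / n) + 2 * k

#' AIC difference reconstructed from coefficients of determination
#'
#' With a common response, \eqn{RSS = (1 - R^2)\,SS_{tot}} so
#' \eqn{AIC_m - AIC_{ref} = n[\ln(1-R^2_m) - \ln(1-R^2_{ref})] + 2(k_m - k_{ref})};
#' the total sum of squares cancels. Lets published model-selection tables
#' be checked from their printed \eqn{R^2} alone.
#'
#' @param r2 R-squared of the model of interest
#' @param r2_ref R-squared of the reference (best) model
#' @param n effective sample size
#' @param k,k_ref mean-parameter counts of the two models
#' @return \eqn{\Delta AIC} relative to the reference model
#' @export
delta_aic_from_r2 <- function(r2, r2_ref, n, k, k_ref) {
  n * (log(1 - r2) - log(1 - r2_ref)) + 2 * (k - k_ref)
}

#' Akaike weights from AIC differences
#' @param daic vector of AIC differences (min need not be 0; it is re-based)
#' @return weights summing to 1
#' @export
akaike_weights <- function(daic) {
  d <- daic - min(daic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' The six candidate predictor sets
#'
#' Builds the design of each candidate model from the four elementary
#' predictors: waterway distance, count of barriers with fishpass, count of
#' man-made barriers without fishpass (falls excluded) and the natural-falls
#' indicator/count. The sets are
#' (i) distance;
#' (ii) distance + all barriers;
#' (iii) distance + barriers without fishpass (incl. falls) + barriers with
#' fishpass;
#' (iv) distance + falls;
#' (v) distance + falls + all other barriers;
#' (vi) distance + falls + barriers with fishpass + barriers without
#' fishpass.
#'
#' @param distance,fishpass,no_fishpass,falls aligned numeric vectors (e.g.
#'   \code{offdiag()} of pairwise tables, or per-site upstream profiles)
#' @return named list of data.frames, one per model id \code{i..vi}
#' @export
candidate_designs <- function(distance, fishpass, no_fishpass, falls) {
  stopifnot(length(fishpass) == length(distance),
            length(no_fishpass) == length(distance),
            length(falls) == length(distance))
  list(
    i   = data.frame(distance = distance),
    ii  = data.frame(distance = distance,
                     all_barriers = fishpass + no_fishpass + falls),
    iii = data.frame(distance = distance,
                     no_fishpass_incl_falls = no_fishpass + falls,
                     fishpass = fishpass),
    iv  = data.frame(distance = distance, falls = falls),
    v   = data.frame(distance = distance, falls = falls,
                     other_barriers = fishpass + no_fishpass),
    vi  = data.frame(distance = distance, falls = falls,
                     fishpass = fishpass, no_fishpass = no_fishpass)
  )
}

#' Fit and rank candidate models
#'
#' Ordinary least squares for each candidate design, ranked by AIC computed
#' with \code{n_eff} as sample size. Pairwise responses violate
#' independence; coefficients are reported as fitted (as is conventional)
#' while AIC uses the number of populations and inference is delegated to
#' \code{\link{permutation_pvalues}}.
#'
#' @param response numeric response vector
#' @param designs named list of data.frames (see
#'   \code{\link{candidate_designs}}), all with \code{length(response)} rows
#' @param n_eff effective sample size for AIC
#' @return object of class \code{model_fit_set}: \code{$table} (model, k,
#'   r2, aic, daic, weight), \code{$fits} (lm objects), \code{$n_eff}
#' @export
fit_candidates <- function(response, designs, n_eff) {
  stopifnot(length(designs) >= 1)
  fits <- lapply(designs, function(X) {
    stopifnot(nrow(X) == length(response))
    qrX <- qr(cbind(1, as.matrix(X)))
    if (qrX$rank < ncol(X) + 1)
      stop("singular design (collinear predictors): ",
           paste(names(X), collapse = ", "))
    lm(response ~ ., data = X)
  })
  k <- vapply(fits, function(f) length(coef(f)), 0)
  if (any(n_eff < k + 2)) stop("n_eff too small for some candidate model")
  rss <- vapply(fits, function(f) sum(resid(f)^2), 0)
  sst <- sum((response - mean(response))^2)
  aic <- aic_ls(rss, n_eff, k)
  daic <- aic - min(aic)
  tab <- data.frame(model = names(designs), k = k, r2 = 1 - rss / sst,
                    aic = aic, daic = daic, weight = akaike_weights(daic),
                    row.names = NULL)
  structure(list(table = tab, fits = fits, n_eff = n_eff),
            class = "model_fit_set")
}

#' @export
print.model_fit_set <- function(x, ...) {
  cat("Candidate model selection (n_eff =", x$n_eff, ")\n")
  tab <- x$table
  tab$r2 <- round(tab$r2, 3); tab$aic <- round(tab$aic, 3)
  tab$daic <- round(tab$daic, 3); tab$weight <- round(tab$weight, 3)
  print(tab[order(tab$daic), ], row.names = FALSE)
  invisible(x)
}

#' Freedman-Lane permutation p-values for regression coefficients
#'
#' For each slope, refits the reduced model without that predictor, permutes
#' its residuals onto its fitted values, refits the full model on the
#' reconstructed response and compares |t| statistics:
#' \eqn{p = (1 + \#\{|t^*| \ge |t|\})/(n_{perm}+1)}.
#'
#' @param fit an \code{lm} from \code{\link{fit_candidates}}
#' @param n_perm number of permutations (values below 99 give unstable
#'   p-values and trigger a warning)
#' @return named vector of p-values, one per slope
#' @export
permutation_pvalues <- function(fit, n_perm = 999) {
  if (n_perm < 99) warning("n_perm < 99: permutation p-values are unstable")
  X <- stats::model.matrix(fit)
  y <- stats::model.response(stats::model.frame(fit))
  slopes <- colnames(X)[-1]
  tstat <- function(Xm, yy) {
    f <- stats::lm.fit(Xm, yy)
    rdf <- length(yy) - f$rank
    s2 <- sum(f$residuals^2) / rdf
    XtXinv <- chol2inv(qr.R(f$qr))
    f$coefficients / sqrt(s2 * diag(XtXinv))
  }
  t_obs <- tstat(X, y)
  p <- setNames(numeric(length(slopes)), slopes)
  for (s in slopes) {
    j <- match(s, colnames(X))
    Xr <- X[, -j, drop = FALSE]
    fr <- stats::lm.fit(Xr, y)
    fit_r <- fr$fitted.values; res_r <- fr$residuals
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      ystar <- fit_r + sample(res_r)
      tstar <- tstat(X, ystar)[j]
      if (abs(tstar) >= abs(t_obs[j])) exceed <- exceed + 1L
    }
    p[s] <- (1 + exceed) / (n_perm + 1)
  }
  p
}

#' Commonality analysis of a fitted regression
#'
#' Decomposes the model R-squared into unique and common (shared)
#' contributions per predictor from all-subset regressions. The commonality
#' coefficient of a predictor subset T is
#' \eqn{C(T) = -\sum_{S \subseteq T} (-1)^{|S|} R^2((V \setminus T) \cup S)},
#' whose sum over all non-empty subsets reconstructs the full-model
#' R-squared; \code{unique + common} per predictor equals its squared simple
#' correlation with the response.
#'
#' @param fit an \code{lm} with 1 to 6 predictors
#' @return object of class \code{commonality_decomposition}: \code{$table}
#'   (predictor, unique, common, total, pct_of_r2), \code{$coefficients}
#'   (all subset commonalities), \code{$r2}
#' @export
commonality <- function(fit) {
  X <- stats::model.matrix(fit)[, -1, drop = FALSE]
  y <- stats::model.response(stats::model.frame(fit))
  p <- ncol(X)
  if (p > 6) stop("commonality analysis limited to 6 predictors")
  preds <- colnames(X)
  subsets <- lapply(seq_len(2^p - 1), function(m) which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0))
  r2_of <- function(idx) {
    if (!length(idx)) return(0)
    f <- stats::lm.fit(cbind(1, X[, idx, drop = FALSE]), y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  r2 <- vapply(subsets, r2_of, 0)
  key <- vapply(subsets, function(s) paste(s, collapse = ","), "")
  r2_lookup <- function(idx) if (!length(idx)) 0 else
    r2[match(paste(sort(idx), collapse = ","), key)]
  ## commonality coefficient for each subset T
  cc <- vapply(subsets, function(T) {
    rest <- setdiff(seq_len(p), T)
    ssub <- lapply(seq_len(2^length(T)) - 1, function(m)
      T[bitwAnd(m, 2^(seq_along(T) - 1)) > 0])
    -sum(vapply(ssub, function(S)
      (-1)^length(S) * r2_lookup(c(rest, S)), 0))
  }, 0)
  names(cc) <- vapply(subsets, function(s) paste(preds[s], collapse = "&"), "")
  r2_full <- r2_lookup(seq_len(p))
  tab <- do.call(rbind, lapply(seq_len(p), function(j) {
    inT <- vapply(subsets, function(s) j %in% s, TRUE)
    uni <- cc[inT & lengths(subsets) == 1]
    com <- sum(cc[inT & lengths(subsets) > 1])
    data.frame(predictor = preds[j], unique = unname(uni), common = com,
               total = unname(uni) + com,
               pct_of_r2 = 100 * (unname(uni) + com) / r2_full)
  }))
  structure(list(table = tab, coefficients = cc, r2 = r2_full),
            class = "commonality_decomposition")
}

#' @export
print.commonality_decomposition <- function(x, ...) {
  cat(sprintf("Commonality decomposition (model R2 = %.3f)\n", x$r2))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Virtual distance of a barrier type
#'
#' Expresses a barrier coefficient as the length of uninterrupted river
#' with the same expected effect on the response:
#' \eqn{\beta_{barrier} / \beta_{distance}} km per barrier.
#'
#' @param coefs named coefficient vector (or an \code{lm})
#' @param barrier name of the barrier predictor
#' @param distance name of the distance predictor
#' @return km-equivalent of one barrier
#' @export
virtual_distance <- function(coefs, barrier, distance = "distance") {
  if (inherits(coefs, "lm")) coefs <- coef(coefs)
  if (!all(c(barrier, distance) %in% names(coefs)))
    stop("coefficients must contain '", barrier, "' and '", distance, "'")
  bd <- coefs[[distance]]
  if (is.na(bd) || bd <= 0) {
    warning("distance coefficient is not positive; virtual distance undefined")
    return(NA_real_)
  }
  coefs[[barrier]] / bd
}

#' Candidate models of allelic richness against upstream position
#'
#' Same candidate set and AIC machinery as for pairwise differentiation,
#' with per-site allelic richness as response and upstream distance/typed
#' barrier counts from the reference point as predictors.
#'
#' @param ar data.frame with columns \code{site} and \code{AR} (e.g. from
#'   \code{\link{site_diversity}})
#' @param profile data.frame from \code{\link{upstream_profile}}
#' @return \code{model_fit_set} with \code{n_eff} = number of sites
#' @export
ar_models <- function(ar, profile) {
  m <- merge(ar[, c("site", "AR")], profile, by = "site")
  if (nrow(m) < nrow(ar)) stop("sites missing from upstream profile")
  designs <- candidate_designs(m$distance_km, m$fishpass, m$no_fishpass,
                               m$natural_falls)
  fit_candidates(m$AR, designs, n_eff = nrow(m))
}
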