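## shared toy pairwise predictors: 9 sites on a line with barriers
make_design_fixture <- function(seed = 51, n = 40) {
  set.seed(seed)
  dist <- runif(n, 5, 300)
  fish <- rpois(n, dist / 60)
  nofish <- rpois(n, dist / 150)
  falls <- rbinom(n, 1, 0.3)
  resp <- 1e-4 * dist + 1.2e-3 * fish + 9e-3 * nofish + 1.5e-2 * falls +
    rnorm(n, sd = 0.004)
  list(resp = resp,
       designs = candidate_designs(dist, fish, nofish, falls))
}

test_that("a single candidate gets weight 1 and delta AIC 0", {
  fx <- make_design_fixture()
  ms <- fit_candidates(fx$resp, fx$designs["i"], n_eff = 20)
  expect_equal(ms$table$daic, 0)
  expect_equal(ms$table$weight, 1)
})

test_that("Akaike weights sum to one and respect the AIC ordering", {
  fx <- make_design_fixture()
  ms <- fit_candidates(fx$resp, fx$designs, n_eff = 20)
  expect_equal(sum(ms$table$weight), 1, tolerance = 1e-12)
  expect_equal(order(ms$table$aic), order(-ms$table$weight))
  expect_equal(min(ms$table$daic), 0)
})

test_that("a redundant parameter costs exactly two AIC units at equal RSS", {
  fx <- make_design_fixture()
  ms <- fit_candidates(fx$resp, fx$designs["ii"], n_eff = 20)
  rss <- sum(resid(ms$fits$ii)^2)
  k <- ms$table$k
  ## a duplicated predictor cannot change RSS; only the 2k penalty moves
  expect_equal(aic_ls(rss, 20, k + 1) - aic_ls(rss, 20, k), 2)
  ## and the exact duplicate itself is refused by the collinearity guard
  d3 <- fx$designs$ii; d3$dup <- d3$distance
  expect_error(fit_candidates(fx$resp, list(bad = d3), n_eff = 20),
               "singular design")
})

test_that("permutation p-values are deterministic given the seed, tiny for
          planted effects and well-behaved for noise", {
  fx <- make_design_fixture(seed = 57, n = 47)
  X <- fx$designs$iii
  X$noise <- rnorm(47)
  fit <- lm(fx$resp ~ ., data = X)
  set.seed(5); p1 <- permutation_pvalues(fit, n_perm = 499)
  set.seed(5); p2 <- permutation_pvalues(fit, n_perm = 499)
  expect_identical(p1, p2)
  expect_lte(p1[["no_fishpass_incl_falls"]], 0.01)
  expect_gte(p1[["noise"]], 0.05)
  expect_warning(permutation_pvalues(fit, n_perm = 50), "unstable")
})

test_that("the permutation test is calibrated for a null predictor", {
  set.seed(61)
  ps <- replicate(120, {
    x <- rnorm(30); z <- rnorm(30); y <- 0.5 * z + rnorm(30)
    fit <- lm(y ~ z + x)
    permutation_pvalues(fit, n_perm = 99)[["x"]]
  })
  rej <- mean(ps <= 0.05)
  expect_lt(abs(rej - 0.05), 2.58 * sqrt(0.05 * 0.95 / 120) + 0.01)
})

test_that("commonality reconstructs R2 and matches the 3-predictor oracle", {
  set.seed(67)
  n <- 60
  x1 <- rnorm(n); x2 <- 0.6 * x1 + rnorm(n); x3 <- rnorm(n)
  y <- x1 + 0.5 * x2 - 0.8 * x3 + rnorm(n)
  fit <- lm(y ~ x1 + x2 + x3)
  cm <- commonality(fit)
  o <- commonality_oracle_3(y, x1, x2, x3)
  expect_equal(cm$table$unique, o$unique, tolerance = 1e-10)
  expect_equal(sum(cm$coefficients), o$r2, tolerance = 1e-10)
  expect_equal(cm$coefficients[["x1&x2"]], o$common12, tolerance = 1e-10)
  expect_equal(cm$coefficients[["x1&x2&x3"]], o$common123, tolerance = 1e-10)
  ## total per predictor = squared simple correlation with the response
  expect_equal(cm$table$total,
               c(cor(y, x1)^2, cor(y, x2)^2, cor(y, x3)^2),
               tolerance = 1e-10)
})

test_that("orthogonal predictors have zero common variance", {
  set.seed(71)
  n <- 50
  x1 <- rnorm(n)
  x2 <- resid(lm(rnorm(n) ~ x1))       # exactly orthogonal in-sample
  y <- x1 + x2 + rnorm(n)
  ## center y-projections: orthogonality in covariance makes commons ~ 0
  cm <- commonality(lm(y ~ x1 + x2))
  expect_lt(abs(cm$table$common[1]), 1e-10)
  expect_equal(cm$table$unique[1], cor(y, x1)^2, tolerance = 1e-10)
  one <- commonality(lm(y ~ x1))
  expect_equal(one$table$unique, one$r2, tolerance = 1e-12)
  expect_equal(one$table$common, 0, tolerance = 1e-12)
})

test_that("virtual distance is a coefficient ratio with unit bookkeeping", {
  co <- c(`(Intercept)` = 0.01, distance = 1.122e-4,
          no_fishpass = 1.149e-2, zero = 0)
  expect_equal(virtual_distance(co, "no_fishpass"), 1.149e-2 / 1.122e-4)
  expect_equal(virtual_distance(co, "zero"), 0)
  ## rescaling distance to metres leaves the km-equivalent unchanged
  co_m <- co; co_m[["distance"]] <- co[["distance"]] / 1000
  expect_equal(virtual_distance(co_m, "no_fishpass") / 1000,
               virtual_distance(co, "no_fishpass"))
  co_bad <- co; co_bad[["distance"]] <- -1e-5
  expect_warning(vd <- virtual_distance(co_bad, "no_fishpass"), "not positive")
  expect_true(is.na(vd))
})

test_that("allelic-richness models detect a planted barrier-driven decline", {
  net <- example_riverscape()
  prof <- upstream_profile(net, "REF")
  set.seed(73)
  ar <- data.frame(site = prof$site,
                   AR = 8 - 0.25 * prof$no_fishpass - 0.08 * prof$fishpass +
                     rnorm(nrow(prof), sd = 0.15))
  ms <- ar_models(ar, prof)
  best <- ms$table$model[which.min(ms$table$daic)]
  expect_true(best %in% c("iii", "vi"))
  expect_lt(coef(ms$fits$vi)[["no_fishpass"]], 0)
  ## near-constant AR: the distance-only model is typically not beaten
  ## materially (median over noise draws; single draws can be lucky)
  daics <- vapply(1:5, function(s) {
    set.seed(100 + s)
    ar2 <- data.frame(site = prof$site, AR = 7 + rnorm(nrow(prof), sd = 1e-3))
    ms2 <- ar_models(ar2, prof)
    expect_true(all(abs(coef(ms2$fits$vi)[-1]) < 0.01))
    ms2$table$daic[ms2$table$model == "i"]
  }, 0)
  expect_lte(median(daics), 2)
})
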