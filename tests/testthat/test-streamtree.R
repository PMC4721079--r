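## a small dendritic net whose sections all separate some site pair
st_net <- function() {
  nodes <- data.frame(
    node_id = c("J", "S1", "S2", "S3", "S4"),
    kind = c("confluence", rep("site", 4)),
    site_id = c(NA, paste0("S", 1:4)))
  edges <- data.frame(
    edge_id = paste0("e", 1:4), from = "J",
    to = paste0("S", 1:4), length_km = c(2, 3, 4, 5),
    barriers = "", loop = FALSE)
  river_network(nodes, edges)
}

## pairwise sums of per-section values along tree paths
additive_table <- function(net, sites, d) {
  n <- length(sites)
  M <- matrix(0, n, n, dimnames = list(sites, sites))
  for (i in seq_len(n - 1)) for (k in (i + 1):n) {
    pe <- dfs_path_edges(net$edges, sites[i], sites[k])
    M[i, k] <- M[k, i] <- sum(d[pe])
  }
  pairwise_table(M, "FST", sites)
}

test_that("exactly additive distances are recovered with R2 = 1", {
  net <- st_net()
  d_true <- c(e1 = 0.01, e2 = 0, e3 = 0.03, e4 = 0.002)
  fst <- additive_table(net, paste0("S", 1:4), d_true)
  fit <- fit_streamtree(fst, net)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(setNames(fit$sections$d, fit$sections$edge_id),
               d_true, tolerance = 1e-8)
})

test_that("inconsistent star distances match a box-constrained oracle", {
  net <- st_net()
  set.seed(77)
  fst <- additive_table(net, paste0("S", 1:4),
                        c(e1 = 0.01, e2 = 0.004, e3 = 0.03, e4 = 0.002))
  noise <- mat_from_offdiag(rnorm(6, sd = 0.01), 4, paste0("S", 1:4))
  fst <- pairwise_table(unclass(fst) + noise - diag(diag(noise)), "FST",
                        paste0("S", 1:4))
  fit <- fit_streamtree(fst, net)
  ## oracle: L-BFGS-B on the 4-parameter quadratic with lower bounds 0
  A <- matrix(0, 6, 4); row <- 0
  sites <- paste0("S", 1:4)
  for (k in 1:3) for (i in (k + 1):4) {
    row <- row + 1
    pe <- dfs_path_edges(net$edges, sites[k], sites[i])
    A[row, match(pe, net$edges$edge_id)] <- 1
  }
  f <- offdiag(fst)
  o <- optim(rep(0.01, 4), function(d) sum((A %*% d - f)^2),
             method = "L-BFGS-B", lower = 0)
  expect_equal(unname(fit$sections$d), o$par, tolerance = 1e-5)
})

test_that("unconstrained residuals are orthogonal to the design", {
  net <- random_tree_net(8, seed = 81)
  sites <- net$nodes$site_id
  set.seed(82)
  fst <- mat_from_offdiag(runif(choose(8, 2), 0, 0.1), 8, sites)
  fit <- fit_streamtree(pairwise_table(fst, "FST", sites), net,
                        constrain_nonneg = FALSE)
  ## residuals r must satisfy A' r = 0 for every estimable group
  r <- offdiag(fit$residuals)
  A <- matrix(0, length(r), length(fit$d_group))
  row <- 0
  for (k in seq_len(7)) for (i in (k + 1):8) {
    row <- row + 1
    pe <- dfs_path_edges(net$edges, sites[k], sites[i])
    g <- unique(fit$sections$group[match(pe, fit$sections$edge_id)])
    A[row, g] <- A[row, g] + 1
  }
  expect_lt(max(abs(crossprod(A, r))), 1e-8)
})

test_that("site order does not affect fitted section distances", {
  net <- random_tree_net(7, seed = 85)
  sites <- net$nodes$site_id
  set.seed(86)
  M <- mat_from_offdiag(runif(choose(7, 2), 0, 0.2), 7, sites)
  f1 <- fit_streamtree(pairwise_table(M, "FST", sites), net)
  perm <- sample(7)
  f2 <- fit_streamtree(pairwise_table(M[perm, perm], "FST", sites[perm]), net)
  expect_equal(f1$sections$d, f2$sections$d, tolerance = 1e-9)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-9)
})

test_that("untraversed sections are flagged, co-traversed ones merged", {
  nodes <- data.frame(
    node_id = c("REF", "C", "M", "S1", "S2"),
    kind = c("reference", "confluence", "confluence", "site", "site"),
    site_id = c(NA, NA, NA, "S1", "S2"))
  edges <- data.frame(
    edge_id = c("down", "a", "b1", "b2"),
    from = c("REF", "C", "C", "M"), to = c("C", "S1", "M", "S2"),
    length_km = c(10, 5, 3, 4), barriers = "", loop = FALSE)
  net <- river_network(nodes, edges)
  fst <- mat_from_offdiag(0.05, 2, c("S1", "S2"))
  expect_error(fit_streamtree(pairwise_table(fst, "FST", c("S1", "S2")), net),
               ">= 3 sites")
  ## add a third site below C, and a dead-arm section no pair traverses
  nodes <- rbind(nodes,
                 data.frame(node_id = c("S0", "X"),
                            kind = c("site", "confluence"),
                            site_id = c("S0", NA)))
  edges <- rbind(edges,
                 data.frame(edge_id = c("c", "dead"),
                            from = "REF", to = c("S0", "X"),
                            length_km = c(2, 6), barriers = "",
                            loop = FALSE))
  net <- river_network(nodes, edges)
  sites <- c("S0", "S1", "S2")
  M <- mat_from_offdiag(c(0.08, 0.1, 0.05), 3, sites)
  fit <- fit_streamtree(pairwise_table(M, "FST", sites), net)
  sec <- fit$sections
  ## b1 and b2 lie on exactly the same paths: merged into one group
  expect_equal(sec$group[sec$edge_id == "b1"],
               sec$group[sec$edge_id == "b2"])
  expect_true(all(sec$identifiable[sec$edge_id %in% c("down", "a", "b1")]))
  ## the dead arm is reported as unidentifiable, not silently zero
  expect_false(sec$identifiable[sec$edge_id == "dead"])
  expect_true(is.na(sec$d[sec$edge_id == "dead"]))
  ## every section distance non-negative under the default constraint
  expect_true(all(sec$d[sec$identifiable] >= -1e-12))
})

test_that("the fit is no worse than a constant-rate strawman", {
  net <- random_tree_net(8, seed = 91)
  sites <- net$nodes$site_id
  set.seed(92)
  M <- mat_from_offdiag(runif(choose(8, 2), 0, 0.15), 8, sites)
  fst <- pairwise_table(M, "FST", sites)
  fit <- fit_streamtree(fst, net)
  ## strawman: every km of river contributes the same genetic distance
  D <- pairwise_river_tables(net, sites)$DISTANCE_KM
  rate <- mean(offdiag(fst)) / mean(offdiag(D))
  pred <- rate * offdiag(D)
  r2_straw <- 1 - sum((offdiag(fst) - pred)^2) /
    sum((offdiag(fst) - mean(offdiag(fst)))^2)
  expect_gte(fit$r2, r2_straw)
})
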