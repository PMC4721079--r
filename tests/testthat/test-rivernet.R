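test_that("distances on a Y-shaped network are path sums", {
  net <- y_network()
  expect_equal(waterway_distance(net, "T1", "T1"), 0)
  expect_equal(waterway_distance(net, "T1", "T2"), 7)
  expect_equal(waterway_distance(net, "T2", "T3"), 9)
  cnt <- barrier_counts(net, "T1", "T2")
  expect_equal(cnt[["FISHPASS"]], 1)
  expect_equal(cnt[["TOTAL"]], 1)
  expect_equal(barrier_counts(net, "T1", "T3")[["TOTAL"]], 0)
})

test_that("distances and counts match a brute-force path search", {
  for (seed in c(2, 5)) {
    net <- random_tree_net(12, seed)
    ids <- net$nodes$node_id
    for (trial in 1:15) {
      ab <- sample(ids, 2)
      pe <- dfs_path_edges(net$edges, ab[1], ab[2])
      expect_equal(waterway_distance(net, ab[1], ab[2]),
                   sum(net$edges$length_km[match(pe, net$edges$edge_id)]))
      onpath <- net$barriers[net$barriers$edge_id %in% pe, ]
      got <- barrier_counts(net, ab[1], ab[2])
      expect_equal(got[["TOTAL"]], nrow(onpath))
      expect_equal(got[["NO_FISHPASS"]], sum(onpath$type == "NO_FISHPASS"))
    }
  }
})

test_that("tree metrics are additive through on-path nodes and symmetric", {
  net <- random_tree_net(10, seed = 8)
  ## find a pair whose path crosses at least one intermediate node
  ids <- net$nodes$node_id
  combos <- combn(ids, 2)
  a <- c <- b <- NA
  for (j in seq_len(ncol(combos))) {
    pe <- dfs_path_edges(net$edges, combos[1, j], combos[2, j])
    if (length(pe) >= 2) {
      a <- combos[1, j]; c <- combos[2, j]
      mid_nodes <- unique(c(net$edges$from[match(pe, net$edges$edge_id)],
                            net$edges$to[match(pe, net$edges$edge_id)]))
      b <- setdiff(mid_nodes, c(a, c))[1]
      break
    }
  }
  expect_equal(waterway_distance(net, a, b) + waterway_distance(net, b, c),
               waterway_distance(net, a, c))
  expect_equal(barrier_counts(net, a, b)[["TOTAL"]] +
                 barrier_counts(net, b, c)[["TOTAL"]],
               barrier_counts(net, a, c)[["TOTAL"]])
  tabs <- pairwise_river_tables(net, net$nodes$site_id)
  for (tb in tabs) expect_identical(unclass(tb), t(unclass(tb)))
})

test_that("removing a barrier never increases any pairwise count", {
  net <- random_tree_net(9, seed = 12)
  tabs <- pairwise_river_tables(net, net$nodes$site_id)
  edges2 <- net$edges
  has_bar <- which(nzchar(edges2$barriers))[1]
  ## drop the first barrier on that edge
  items <- strsplit(edges2$barriers[has_bar], ";")[[1]]
  edges2$barriers[has_bar] <- paste(items[-1], collapse = ";")
  net2 <- river_network(net$nodes, edges2)
  tabs2 <- pairwise_river_tables(net2, net$nodes$site_id)
  expect_true(all(tabs2$BARRIERS_ALL <= tabs$BARRIERS_ALL))
})

test_that("the upstream profile counts what lies below each site", {
  nodes <- data.frame(node_id = c("REF", "S1", "S2"),
                      kind = c("reference", "site", "site"),
                      site_id = c(NA, "S1", "S2"))
  edges <- data.frame(
    edge_id = c("e1", "e2"), from = c("REF", "S1"), to = c("S1", "S2"),
    length_km = c(10, 5),
    barriers = c("f1:FISHPASS:0.2;f2:FISHPASS:0.6;w1:NO_FISHPASS:0.9", ""),
    loop = FALSE)
  net <- river_network(nodes, edges)
  prof <- upstream_profile(net, "REF")
  expect_equal(prof$distance_km, c(10, 15))
  expect_equal(prof$fishpass, c(2, 2))
  expect_equal(prof$no_fishpass, c(1, 1))
  expect_equal(prof$natural_falls, c(0, 0))
  ## site at the reference: distance and counts 0
  prof0 <- upstream_profile(net, "S1", sites = "S1")
  expect_equal(prof0$distance_km, 0)
  expect_equal(prof0$all_barriers, 0)
})

test_that("loop-flagged edges break treeness unless flagged, and routing
          avoids them", {
  nodes <- data.frame(node_id = c("A", "B", "C"),
                      kind = "site", site_id = c("A", "B", "C"))
  edges <- data.frame(edge_id = c("e1", "e2", "e3"),
                      from = c("A", "B", "A"), to = c("B", "C", "C"),
                      length_km = c(1, 1, 10),
                      barriers = "", loop = c(FALSE, FALSE, TRUE))
  net <- river_network(nodes, edges)
  expect_equal(waterway_distance(net, "A", "C"), 2)  # not the 10 km canal
  edges$loop <- FALSE
  expect_error(river_network(nodes, edges), "not a tree")
})

test_that("the synthetic riverscape carries the study's barrier inventory", {
  net <- example_riverscape()
  tot <- barrier_totals(net)
  expect_equal(tot[["FISHPASS"]], 33L)
  expect_equal(tot[["NO_FISHPASS"]], 5L)
  expect_equal(tot[["NATURAL_FALLS"]], 1L)
  ## the falls separate the sites just below and above them
  expect_equal(barrier_counts(net, "R10", "R11")[["NATURAL_FALLS"]], 1)
  expect_equal(barrier_counts(net, "R9", "R10")[["NATURAL_FALLS"]], 0)
})
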