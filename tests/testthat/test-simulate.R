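test_that("migration rates follow the barrier path products", {
  net <- example_riverscape()
  cfg <- sim_config(net, downstream_bias = 2)
  M <- build_migration_matrix(cfg)
  expect_equal(rowSums(M), setNames(rep(1, nrow(M)), rownames(M)))
  ## independent recomputation from the raw edge table
  perm_of <- c(FISHPASS = cfg$p_fishpass, NO_FISHPASS = cfg$p_nofishpass,
               NATURAL_FALLS = cfg$p_falls)
  for (i in sample(nrow(net$edges), 10)) {
    e <- net$edges[i, ]
    items <- strsplit(e$barriers, ";")[[1]]
    types <- vapply(strsplit(items, ":"), `[`, "", 2)
    expected <- cfg$m * prod(perm_of[types])
    got_dn <- M[e$from, e$to]; got_up <- M[e$to, e$from]
    ## one direction carries the full rate, the other the biased rate
    expect_equal(sort(c(got_dn, got_up)),
                 sort(c(expected, expected / 2)), tolerance = 1e-12)
  }
})

test_that("no barriers and no bias give symmetric rates; an impermeable
          barrier gives zero", {
  net <- two_deme_net()
  M <- build_migration_matrix(sim_config(net, m = 0.05, downstream_bias = 1))
  expect_equal(M["D1", "D2"], 0.05)
  expect_equal(M["D2", "D1"], 0.05)
  net_b <- two_deme_net("w:NO_FISHPASS:0.5")
  M0 <- build_migration_matrix(sim_config(net_b, p_nofishpass = 0,
                                          downstream_bias = 1))
  expect_equal(M0["D1", "D2"], 0)
  expect_equal(diag(M0), c(D1 = 1, D2 = 1))
})

test_that("an over-connected node with too much migration is refused", {
  net <- y_network()
  expect_error(build_migration_matrix(sim_config(net, m = 0.4,
                                                 downstream_bias = 1)),
               "self-rate")
})

test_that("the same seed reproduces the dataset exactly", {
  cfg <- sim_config(two_deme_net(), N = 30, burnin = 50, n_loci = 3,
                    sample_size = 10, seed = 11)
  d1 <- run_forward(cfg); d2 <- run_forward(cfg)
  expect_identical(d1$alleles, d2$alleles)
  expect_identical(d1$ind, d2$ind)
  cfg$seed <- 12
  d3 <- run_forward(cfg)
  expect_false(identical(d1$alleles, d3$alleles))
})

test_that("sampling more fish than a deme holds is an error", {
  expect_error(sim_config(two_deme_net(), N = 20, sample_size = 45),
               "exceeds deme size")
})

test_that("isolated demes drift to strong differentiation", {
  set.seed(15)
  th <- replicate(5, {
    cfg <- sim_config(two_deme_net(), N = 50, m = 0, mu = 0, n_loci = 5,
                      burnin = 600, sample_size = 40,
                      founder_freqs = diverse_founders(),
                      seed = sample.int(1e6, 1))
    wc_theta(run_forward(cfg))$theta
  })
  expect_gte(median(th), 0.5)
})

test_that("two-deme equilibrium theta matches the coalescent expectation", {
  ## N = 100, m = 0.025 per deme: for n = 2 demes
  ## FST = (1/(2m)) / (2N*n + 1/(2m)) = 1/(1 + 8Nm); mutation pushes the
  ## realized value slightly below. Band: +/- 50%.
  set.seed(19)
  th <- replicate(60, {
    cfg <- sim_config(two_deme_net(), N = 100, m = 0.025,
                      downstream_bias = 1, mu = 5e-4, n_loci = 9,
                      burnin = 1000, sample_size = 50,
                      seed = sample.int(1e6, 1))
    wc_theta(run_forward(cfg))$theta
  })
  expected <- 1 / (1 + 8 * 100 * 0.025)
  expect_gt(mean(th), expected / 2)
  expect_lt(mean(th), expected * 1.5)
})

test_that("burn-in zero founders are in Hardy-Weinberg and linkage
          equilibrium", {
  cfg <- sim_config(chain_riverscape(4), N = 60, burnin = 0, n_loci = 5,
                    sample_size = 60, seed = 23)
  ds <- run_forward(cfg)
  div <- site_diversity(ds, fis_perm = 99)
  expect_true(all(abs(div$Fis) < 0.25))
  expect_gte(min(div$Fis_p), 0.0001)
  ## no drift signal either
  e <- ld_ne(ds, "S1")
  expect_gt(e$ne, 100)
})

test_that("a stronger planted contrast is recovered more cleanly", {
  ## small riverscape for speed: 8 demes in a line, middle edge barriered
  ids <- paste0("S", 1:8)
  nodes <- data.frame(node_id = c("REF", ids),
                      kind = c("reference", rep("site", 8)),
                      site_id = c(NA, ids))
  bar <- c("", "f1:FISHPASS:0.5", "", "w1:NO_FISHPASS:0.5", "",
           "f2:FISHPASS:0.5", "", "w2:NO_FISHPASS:0.5")
  edges <- data.frame(edge_id = paste0("e", 1:8),
                      from = c("REF", ids[1:7]), to = ids[1:8],
                      length_km = 10, barriers = bar, loop = FALSE)
  net <- river_network(nodes, edges)
  run_grid <- function(p_nf, n_rep = 6) {
    diffs <- replicate(n_rep, {
      cfg <- sim_config(net, N = 100, m = 0.1, p_nofishpass = p_nf,
                        p_fishpass = 0.7, burnin = 500, n_loci = 9,
                        sample_size = 40, seed = sample.int(1e6, 1))
      rec <- run_forward(cfg)
      fst <- pairwise_fst(rec)
      tabs <- pairwise_river_tables(net, site_ids(rec))
      designs <- candidate_designs(offdiag(tabs$DISTANCE_KM),
                                   offdiag(tabs$BARRIERS_FISHPASS),
                                   offdiag(tabs$BARRIERS_NOFISHPASS),
                                   offdiag(tabs$RHINEFALLS))
      ## falls column is constant zero here: drop falls models
      ms <- fit_candidates(offdiag(fst), designs["iii"], length(site_ids(rec)))
      co <- coef(ms$fits$iii)
      co[["no_fishpass_incl_falls"]] - co[["fishpass"]]
    })
    mean(diffs)
  }
  set.seed(27)
  weak <- run_grid(p_nf = 0.7)    # no contrast planted
  strong <- run_grid(p_nf = 0.1)
  expect_gt(strong, weak)
  expect_gt(strong, 0)
})
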