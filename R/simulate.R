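## Forward-time stepping-stone simulator on a dendritic river network.
## Demes sit on every node (the river is populated everywhere); migration is
## restricted to adjacent demes, attenuated by the permeabilities of the
## barriers on the connecting section and biased downstream (larval drift).
## Microsatellites evolve by stepwise mutation with reflecting bounds.

#' Simulation configuration
#'
#' Defaults describe a study-like riverscape: demes of 200 diploids, 10%
#' baseline exchange with each neighbouring deme per generation, fishpasses
#' passing 70% of would-be migrants, man-made barriers without fishpass 10%,
#' the natural falls 5%, a modest 1.5-fold downstream bias from larval
#' drift, and nine microsatellites mutating at 5e-4 per generation.
#'
#' @param network river_network; demes are created on every node
#' @param N diploid deme size
#' @param m baseline per-generation migration rate to each adjacent deme
#' @param p_fishpass,p_nofishpass,p_falls permeability multipliers in
#'   \[0, 1\] applied per barrier crossed, by barrier type
#' @param downstream_bias factor >= 1 dividing upstream movement
#' @param mu stepwise mutation rate per allele copy per generation
#' @param n_loci number of unlinked microsatellite loci
#' @param burnin generations to run (>= 10 N recommended for near-
#'   equilibrium structure)
#' @param sample_size diploids sampled per site (<= N)
#' @param founder_alleles integer allele states founders are drawn from
#'   uniformly (iid per copy); \code{founder_freqs} overrides with a list
#'   (one named numeric vector of frequencies per locus, recycled)
#' @param founder_freqs optional list of named frequency vectors
#' @param allele_bounds reflecting bounds of the stepwise mutation model
#' @param seed RNG seed recorded in the config
#' @return object of class \code{sim_config}
#' @export
sim_config <- function(network, N = 200, m = 0.1, p_fishpass = 0.7,
                       p_nofishpass = 0.1, p_falls = 0.05,
                       downstream_bias = 1.5, mu = 5e-4, n_loci = 9,
                       burnin = 10 * N, sample_size = 45,
                       founder_alleles = 25:36, founder_freqs = NULL,
                       allele_bounds = c(5L, 60L), seed = 1) {
  stopifnot(inherits(network, "river_network"), N >= 2,
            m >= 0, m <= 1, mu >= 0, mu <= 1, downstream_bias >= 1,
            p_fishpass >= 0, p_fishpass <= 1,
            p_nofishpass >= 0, p_nofishpass <= 1,
            p_falls >= 0, p_falls <= 1, n_loci >= 1, burnin >= 0)
  if (sample_size > N) stop("sample_size exceeds deme size N")
  structure(list(network = network, N = as.integer(N), m = m,
                 p_fishpass = p_fishpass, p_nofishpass = p_nofishpass,
                 p_falls = p_falls, downstream_bias = downstream_bias,
                 mu = mu, n_loci = as.integer(n_loci),
                 burnin = as.integer(burnin),
                 sample_size = as.integer(sample_size),
                 founder_alleles = as.integer(founder_alleles),
                 founder_freqs = founder_freqs,
                 allele_bounds = as.integer(allele_bounds), seed = seed),
            class = "sim_config")
}

## reference node used to orient the network (downstream anchor)
reference_node <- function(net) {
  r <- net$nodes$node_id[net$nodes$kind == "reference"]
  if (length(r) == 1) return(r)
  NULL
}

#' Per-generation migration matrix between demes
#'
#' Backward migration rates: entry \code{[d, s]} is the probability that an
#' offspring born in deme d has its parents in deme s. Adjacent demes
#' exchange at rate \code{m} multiplied by the product of permeabilities of
#' all barriers on the connecting section; movement in the upstream
#' direction (away from the reference node) is additionally divided by the
#' downstream-bias factor. Rows are completed with the self-rate
#' \code{1 - sum(others)}; a negative self-rate (m too large for the node
#' degree) is an error.
#'
#' @param cfg sim_config
#' @return deme x deme rate matrix with node ids as dimnames
#' @export
build_migration_matrix <- function(cfg) {
  net <- cfg$network
  demes <- net$nodes$node_id
  nd <- length(demes)
  M <- matrix(0, nd, nd, dimnames = list(demes, demes))
  ref <- reference_node(net)
  depth <- if (!is.null(ref)) {
    igraph::distances(net$tree, v = ref, weights = NA)[1, demes]
  } else setNames(rep(0, nd), demes)   # no reference: no orientation
  perm_of <- c(FISHPASS = cfg$p_fishpass, NO_FISHPASS = cfg$p_nofishpass,
               NATURAL_FALLS = cfg$p_falls)
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    if (isTRUE(e$loop)) next
    bt <- net$barriers$type[net$barriers$edge_id == e$edge_id]
    perm <- prod(perm_of[bt])
    if (!length(bt)) perm <- 1
    up <- if (depth[e$from] >= depth[e$to]) e$from else e$to
    dn <- if (up == e$from) e$to else e$from
    ## offspring in the upstream deme with downstream parents = upstream
    ## movement of fish, penalized by the drift bias
    M[up, dn] <- M[up, dn] + cfg$m * perm / cfg$downstream_bias
    M[dn, up] <- M[dn, up] + cfg$m * perm
  }
  diag(M) <- 0
  self <- 1 - rowSums(M)
  if (any(self < 0))
    stop("negative self-rate: m too large for node degree at ",
         paste(demes[self < 0], collapse = ", "))
  diag(M) <- self
  M
}

#' Run the forward simulation
#'
#' Wright-Fisher demes with migration at reproduction, non-overlapping
#' generations and stepwise mutation (reflecting bounds). Deterministic
#' given \code{cfg$seed}. Founders are drawn iid from
#' \code{founder_alleles} (or \code{founder_freqs}); \code{burnin}
#' generations are then simulated before sampling \code{sample_size}
#' individuals without replacement at every site node.
#'
#' @param cfg sim_config
#' @return \code{genotype_dataset} of the sampled individuals; the config
#'   is attached as attribute \code{"config"}
#' @export
run_forward <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  net <- cfg$network
  demes <- net$nodes$node_id
  nd <- length(demes)
  M <- build_migration_matrix(cfg)
  mig_cum <- t(apply(M, 1, cumsum))
  nl <- cfg$n_loci; N <- cfg$N
  sz <- nl * 2L * N * nd
  state <- if (is.null(cfg$founder_freqs)) {
    sample(cfg$founder_alleles, sz, replace = TRUE)
  } else {
    ff <- rep(cfg$founder_freqs, length.out = nl)
    st <- integer(sz)
    ## layout: l + nl*(c + 2*(i + N*d)); fill per locus
    idx_l <- rep(seq_len(nl), times = sz / nl)
    for (l in seq_len(nl)) {
      f <- ff[[l]]
      st[idx_l == l] <- sample(as.integer(names(f)), sum(idx_l == l),
                               replace = TRUE, prob = f)
    }
    st
  }
  final <- forward_sim_cpp(as.integer(state), nl, N, nd, mig_cum,
                           cfg$burnin, cfg$mu,
                           cfg$allele_bounds[1], cfg$allele_bounds[2])
  dim(final) <- c(nl, 2L, N, nd)

  site_nodes <- which(net$nodes$kind == "site" & !is.na(net$nodes$site_id))
  n_samp <- cfg$sample_size
  total <- n_samp * length(site_nodes)
  arr <- array(NA_integer_, dim = c(total, nl, 2L))
  ids <- sites <- character(total)
  row <- 0L
  for (v in site_nodes) {
    sid <- net$nodes$site_id[v]
    pick <- sample(N, n_samp)
    for (i in pick) {
      row <- row + 1L
      arr[row, , 1] <- final[, 1, i, v]
      arr[row, , 2] <- final[, 2, i, v]
      ids[row] <- paste0(sid, "_", row)
      sites[row] <- sid
    }
  }
  ds <- genotype_dataset(arr, paste0("L", seq_len(nl)),
                         data.frame(id = ids, site = sites))
  attr(ds, "config") <- cfg
  ds
}

## helper used by example_riverscape(): chain of nodes joined by sections
chain_edges <- function(nodes, lengths, barriers) {
  data.frame(edge_id = paste0("e_", nodes[-length(nodes)], "_", nodes[-1]),
             from = nodes[-length(nodes)], to = nodes[-1],
             length_km = lengths, barriers = barriers, loop = FALSE)
}

#' Synthetic fragmented riverscape
#'
#' A fixed dendritic network emulating the structure of a heavily dammed
#' lowland catchment: a main stem with a natural falls high up, one large
#' tributary carrying most sites, and two smaller tributaries, 40 demes in
#' total (36 sampling sites plus confluences), fragmented by 33 barriers
#' with fishpass, 5 without and the falls. Entirely synthetic: topology,
#' lengths and barrier placements are invented to mirror the statistical
#' setting (collinearity of distance and barrier counts, barrier-free
#' stretches, a barrier-dense tributary), not any real river geometry.
#'
#' @return river_network with a reference node \code{REF} at the downstream
#'   end of the main stem
#' @export
example_riverscape <- function() {
  main <- c("REF", paste0("R", 1:13))
  aar <- paste0("A", 1:12)
  reuss <- paste0("Re", 1:5)
  limmat <- paste0("L", 1:6)
  nodes <- data.frame(
    node_id = c(main, "C_A", aar, "C_Re", reuss, "C_L", limmat),
    kind = c("reference", rep("site", 13), "confluence", rep("site", 12),
             "confluence", rep("site", 5), "confluence", rep("site", 6)),
    site_id = c(NA, main[-1], NA, aar, NA, reuss, NA, limmat))

  fp <- function(id) paste0(id, ":FISHPASS:0.5")
  nf <- function(id) paste0(id, ":NO_FISHPASS:0.5")

  ## main stem: mostly fishpass barriers, the falls between R10 and R11,
  ## one fishpass-free station low down; a couple of free-flowing sections
  main_bar <- c(fp("b1"), fp("b2"), "", fp("b3"), nf("b4"), fp("b5"),
                fp("b6"), fp("b7"), "", fp("b8"),
                "falls:NATURAL_FALLS:0.4", fp("b9"), fp("b10"))
  main_len <- c(9, 14, 11, 16, 12, 10, 15, 13, 8, 12, 6, 18, 14)
  e_main <- chain_edges(main, main_len, main_bar)

  ## large tributary joining between R2 and R3 is modelled by hanging the
  ## confluence C_A off R2; its own chain carries many fishpass barriers
  ## and one without
  e_ca <- data.frame(edge_id = "e_R2_C_A", from = "R2", to = "C_A",
                     length_km = 4, barriers = "", loop = FALSE)
  aar_bar <- c(fp("b11"), fp("b12"), "", fp("b13"), fp("b14"), fp("b15"),
               nf("b16"), fp("b17"), "", fp("b18"), fp("b19"), fp("b20"))
  aar_len <- c(7, 12, 15, 10, 13, 9, 11, 16, 12, 8, 14, 10)
  e_aar <- chain_edges(c("C_A", aar), aar_len, aar_bar)

  ## small tributary of the large one, fishpass-free station at its mouth
  e_cre <- data.frame(edge_id = "e_A4_C_Re", from = "A4", to = "C_Re",
                      length_km = 3, barriers = nf("b21"), loop = FALSE)
  reuss_bar <- c(fp("b22"), "", fp("b23"), fp("b24"), fp("b25"))
  reuss_len <- c(8, 11, 9, 12, 10)
  e_reuss <- chain_edges(c("C_Re", reuss), reuss_len, reuss_bar)

  ## barrier-dense tributary close to the river mouth: short distances but
  ## many barriers, two of them without fishpass
  e_cl <- data.frame(edge_id = "e_R1_C_L", from = "R1", to = "C_L",
                     length_km = 3, barriers = "", loop = FALSE)
  lim_bar <- c(fp("b26"), nf("b27"), fp("b28"), fp("b29"), nf("b30"),
               fp("b31"))
  lim_len <- c(5, 6, 7, 5, 6, 8)
  e_lim <- chain_edges(c("C_L", limmat), lim_len, lim_bar)

  ## remaining fishpass stations: two on previously free-flowing sections,
  ## and second stations on the longest sections (33 with fishpass in all)
  e_aar$barriers[3] <- fp("b32")
  e_main$barriers[3] <- fp("b33")
  e_main$barriers[4] <- paste(e_main$barriers[4], fp("b34"), sep = ";")
  e_main$barriers[8] <- paste(e_main$barriers[8], fp("b35"), sep = ";")
  e_aar$barriers[8] <- paste(e_aar$barriers[8], fp("b36"), sep = ";")
  e_aar$barriers[11] <- paste(e_aar$barriers[11], fp("b37"), sep = ";")
  e_lim$barriers[4] <- paste(e_lim$barriers[4], fp("b38"), sep = ";")

  river_network(nodes, rbind(e_main, e_ca, e_aar, e_cre, e_reuss, e_cl, e_lim))
}

#' Linear chain riverscape
#'
#' Minimal dendritic network: \code{n_sites} site nodes in a line above a
#' downstream reference node, equal section lengths, no barriers. Useful
#' for null simulations (with \code{burnin = 0} the founders are drawn iid,
#' giving exact Hardy-Weinberg and linkage equilibrium within sites) and as
#' a scaffold for toy examples.
#'
#' @param n_sites number of site nodes
#' @param length_km section length
#' @return river_network
#' @export
chain_riverscape <- function(n_sites, length_km = 10) {
  ids <- paste0("S", seq_len(n_sites))
  nodes <- data.frame(node_id = c("REF", ids),
                      kind = c("reference", rep("site", n_sites)),
                      site_id = c(NA, ids))
  river_network(nodes, chain_edges(c("REF", ids), rep(length_km, n_sites), ""))
}

#' Parameter-recovery experiment
#'
#' Runs the full pipeline (simulate, pairwise F_ST, river tables, candidate
#' regressions) on replicate simulated datasets and reports how often the
#' planted barrier-type contrast is recovered: the no-fishpass coefficient
#' exceeding the fishpass coefficient (both positive, model iii), and the
#' barrier-aware models (iii or vi) outranking the distance-only model (i)
#' by more than 2 AIC units.
#'
#' @param cfg sim_config (replicate r uses seed \code{cfg$seed + r})
#' @param n_rep number of replicates
#' @return list: \code{replicates} data.frame (coefficients, daic_i,
#'   best_model per replicate), \code{frac_order_strict} (beta_nofish >
#'   beta_fish > 0), \code{frac_order} (beta_nofish > beta_fish),
#'   \code{frac_barrier_model} (iii/vi beat i by > 2 AIC)
#' @export
recovery_experiment <- function(cfg, n_rep = 50) {
  net <- cfg$network
  sites <- net$nodes$site_id[net$nodes$kind == "site" & !is.na(net$nodes$site_id)]
  tabs <- pairwise_river_tables(net, sites)
  designs <- candidate_designs(offdiag(tabs$DISTANCE_KM),
                               offdiag(tabs$BARRIERS_FISHPASS),
                               offdiag(tabs$BARRIERS_NOFISHPASS),
                               offdiag(tabs$RHINEFALLS))
  reps <- lapply(seq_len(n_rep), function(r) {
    cfg_r <- cfg; cfg_r$seed <- cfg$seed + r
    ds <- run_forward(cfg_r)
    fst <- pairwise_fst(ds)
    fst <- fst[sites, sites]
    ms <- fit_candidates(offdiag(fst), designs, n_eff = length(sites))
    co <- coef(ms$fits$iii)
    daic_i <- ms$table$daic[ms$table$model == "i"] -
      min(ms$table$daic[ms$table$model %in% c("iii", "vi")])
    data.frame(rep = r,
               beta_nofish = co[["no_fishpass_incl_falls"]],
               beta_fish = co[["fishpass"]],
               daic_i_vs_barrier = daic_i,
               best_model = ms$table$model[which.min(ms$table$daic)])
  })
  reps <- do.call(rbind, reps)
  list(replicates = reps,
       frac_order_strict = mean(reps$beta_nofish > reps$beta_fish &
                                  reps$beta_fish > 0),
       frac_order = mean(reps$beta_nofish > reps$beta_fish),
       frac_barrier_model = mean(reps$daic_i_vs_barrier > 2))
}
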