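## Shared fixtures and independent oracles. Oracles deliberately use naive
## scalar arithmetic / exhaustive enumeration, not the package's vectorized
## code paths.

## dataset from a data.frame with columns site, id (optional) and one
## column per locus holding "a/b" strings (NA = missing)
toy_ds <- function(df) {
  loci <- setdiff(names(df), c("site", "id"))
  n <- nrow(df)
  arr <- array(NA_integer_, dim = c(n, length(loci), 2L))
  for (j in seq_along(loci)) {
    parts <- strsplit(as.character(df[[loci[j]]]), "/")
    for (i in seq_len(n)) {
      if (!is.na(df[[loci[j]]][i]))
        arr[i, j, ] <- as.integer(parts[[i]])
    }
  }
  ids <- if ("id" %in% names(df)) df$id else paste0("i", seq_len(n))
  genotype_dataset(arr, loci, data.frame(id = ids, site = df$site))
}

## iid random dataset (no structure)
rand_ds <- function(n_sites = 3, n_ind = 10, n_loci = 4, n_alleles = 5,
                    miss = 0, seed = 1) {
  set.seed(seed)
  n <- n_sites * n_ind
  arr <- array(sample(100L + seq_len(n_alleles), n * n_loci * 2, TRUE),
               dim = c(n, n_loci, 2L))
  if (miss > 0) {
    drop <- which(matrix(runif(n * n_loci) < miss, n, n_loci), arr.ind = TRUE)
    for (r in seq_len(nrow(drop))) arr[drop[r, 1], drop[r, 2], ] <- NA
  }
  genotype_dataset(arr, paste0("L", seq_len(n_loci)),
                   data.frame(id = paste0("i", seq_len(n)),
                              site = rep(paste0("P", seq_len(n_sites)),
                                         each = n_ind)))
}

## Y-shaped river: junction J with three legs of 3, 4, 5 km to tips
y_network <- function() {
  nodes <- data.frame(node_id = c("J", "T1", "T2", "T3"),
                      kind = c("confluence", "site", "site", "site"),
                      site_id = c(NA, "T1", "T2", "T3"))
  edges <- data.frame(edge_id = c("e1", "e2", "e3"),
                      from = "J", to = c("T1", "T2", "T3"),
                      length_km = c(3, 4, 5),
                      barriers = c("", "w1:FISHPASS:0.5", ""),
                      loop = FALSE)
  river_network(nodes, edges)
}

## random tree network: each node attaches to a random earlier node
random_tree_net <- function(n_nodes, seed) {
  set.seed(seed)
  ids <- paste0("N", seq_len(n_nodes))
  from <- ids[vapply(2:n_nodes, function(i) sample(i - 1, 1), 0L)]
  types <- c("FISHPASS", "NO_FISHPASS", "NATURAL_FALLS")
  bar <- vapply(2:n_nodes, function(i) {
    k <- sample(0:2, 1)
    if (k == 0) return("")
    paste(sprintf("b%d_%d:%s:0.5", i, seq_len(k),
                  sample(types, k, TRUE)), collapse = ";")
  }, "")
  edges <- data.frame(edge_id = paste0("e", 2:n_nodes), from = from,
                      to = ids[-1],
                      length_km = round(runif(n_nodes - 1, 1, 20), 2),
                      barriers = bar, loop = FALSE)
  nodes <- data.frame(node_id = ids, kind = "site", site_id = ids)
  river_network(nodes, edges)
}

## brute-force path finder by depth-first search over the raw edge list
dfs_path_edges <- function(edges, a, b) {
  if (a == b) return(character(0))
  adj <- rbind(data.frame(n1 = edges$from, n2 = edges$to, e = edges$edge_id),
               data.frame(n1 = edges$to, n2 = edges$from, e = edges$edge_id))
  search <- function(node, target, visited) {
    if (node == target) return(character(0))
    out <- adj[adj$n1 == node & !(adj$n2 %in% visited), , drop = FALSE]
    for (r in seq_len(nrow(out))) {
      sub <- search(out$n2[r], target, c(visited, node))
      if (!is.null(sub)) return(c(out$e[r], sub))
    }
    NULL
  }
  search(a, b, character(0))
}

## naive Weir-Cockerham (1984) components, scalar loops straight from the
## definitional formulas; pops = list of two-column allele matrices
wc_oracle <- function(pops) {
  pops <- lapply(pops, function(m) m[!is.na(m[, 1]), , drop = FALSE])
  loci_alleles <- sort(unique(unlist(lapply(pops, c))))
  r <- length(pops)
  n <- sapply(pops, nrow)
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  A <- B <- C <- 0
  for (al in loci_alleles) {
    p <- sapply(pops, function(m) sum(m == al) / (2 * nrow(m)))
    h <- sapply(pops, function(m)
      sum((m[, 1] == al) != (m[, 2] == al)) / nrow(m))
    pbar <- sum(n * p) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) next
    ssq <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    A <- A + (nbar / nc) *
      (ssq - 1 / (nbar - 1) *
         (pbar * (1 - pbar) - (r - 1) / r * ssq - hbar / 4))
    B <- B + (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * ssq -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    C <- C + hbar / 2
  }
  list(a = A, b = B, c = C, theta = A / (A + B + C))
}

## commonality coefficients for exactly three predictors, written out as
## the textbook inclusion-exclusion identities over the seven subset R2s
commonality_oracle_3 <- function(y, x1, x2, x3) {
  r2 <- function(...) {
    f <- lm.fit(cbind(1, ...), y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  R1 <- r2(x1); R2 <- r2(x2); R3 <- r2(x3)
  R12 <- r2(x1, x2); R13 <- r2(x1, x3); R23 <- r2(x2, x3)
  R123 <- r2(x1, x2, x3)
  u1 <- R123 - R23; u2 <- R123 - R13; u3 <- R123 - R12
  c12 <- R13 + R23 - R3 - R123
  c13 <- R12 + R23 - R2 - R123
  c23 <- R12 + R13 - R1 - R123
  ## c123 from the identity: all seven components sum to R123
  c123 <- R123 - (u1 + u2 + u3 + c12 + c13 + c23)
  list(unique = c(u1, u2, u3), common12 = c12, common13 = c13,
       common23 = c23, common123 = c123, r2 = R123)
}

## single-deme and two-deme networks for simulator-based oracles
single_deme_net <- function() {
  river_network(
    data.frame(node_id = "D1", kind = "site", site_id = "D1"),
    data.frame(edge_id = character(0), from = character(0),
               to = character(0), length_km = numeric(0),
               barriers = character(0), loop = logical(0)))
}

two_deme_net <- function(barriers = "") {
  river_network(
    data.frame(node_id = c("D1", "D2"), kind = "site",
               site_id = c("D1", "D2")),
    data.frame(edge_id = "e1", from = "D1", to = "D2", length_km = 10,
               barriers = barriers, loop = FALSE))
}

## founder pool used when simulating at small Ne without mutation-drift
## equilibrium: eight equifrequent alleles
diverse_founders <- function() list(setNames(rep(1 / 8, 8), 20:27))

## all n! permutations of 1:n as rows (recursive enumeration)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

## build a symmetric pairwise table from an off-diagonal vector
mat_from_offdiag <- function(v, n, sites = paste0("S", seq_len(n))) {
  M <- matrix(0, n, n, dimnames = list(sites, sites))
  M[lower.tri(M)] <- v
  M + t(M)
}
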