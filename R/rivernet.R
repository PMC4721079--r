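## Dendritic river-network model: waterway distances along the tree, typed
## barrier counts between site pairs, and upstream profiles from a
## downstream reference point. Loop-creating edges (e.g. a canal) are
## carried but excluded from routing unless explicitly requested.

BARRIER_TYPES <- c("FISHPASS", "NO_FISHPASS", "NATURAL_FALLS")

#' Build a river network
#'
#' @param nodes data.frame with columns \code{node_id}, \code{kind}
#'   (\code{"site"}, \code{"confluence"} or \code{"reference"}) and
#'   \code{site_id} (NA for non-site nodes)
#' @param edges data.frame with columns \code{edge_id}, \code{from},
#'   \code{to}, \code{length_km} (> 0), \code{barriers} (string
#'   \code{"id:TYPE:pos;..."}, empty for none) and optional logical
#'   \code{loop} flagging edges that close a loop in the drainage
#' @return object of class \code{river_network}
#' @export
river_network <- function(nodes, edges) {
  stopifnot(all(c("node_id", "kind") %in% names(nodes)),
            all(c("edge_id", "from", "to", "length_km") %in% names(edges)))
  if (!"site_id" %in% names(nodes)) nodes$site_id <- NA_character_
  if (!"barriers" %in% names(edges)) edges$barriers <- ""
  if (!"loop" %in% names(edges)) edges$loop <- FALSE
  edges$loop <- as.logical(edges$loop) %in% TRUE
  if (any(edges$length_km <= 0)) stop("edge lengths must be > 0")
  if (!all(c(edges$from, edges$to) %in% nodes$node_id))
    stop("edge endpoints must be declared nodes")
  sid <- nodes$site_id[!is.na(nodes$site_id) & nzchar(nodes$site_id)]
  if (anyDuplicated(sid)) stop("each site_id may map to only one node")

  bar <- parse_barriers(edges)
  if (!all(bar$type %in% BARRIER_TYPES))
    stop("unknown barrier type(s): ",
         paste(setdiff(bar$type, BARRIER_TYPES), collapse = ", "))

  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = nodes$node_id)
  igraph::E(g)$edge_id <- edges$edge_id
  igraph::E(g)$weight <- edges$length_km
  igraph::E(g)$loop_flag <- edges$loop
  if (!igraph::is_connected(g)) stop("network must be connected")
  tr <- igraph::subgraph_from_edges(g, igraph::E(g)[!igraph::E(g)$loop_flag],
                                    delete.vertices = FALSE)
  if (igraph::ecount(tr) != igraph::vcount(tr) - 1 || !igraph::is_connected(tr))
    stop("network is not a tree after removing loop-flagged edges")
  structure(list(nodes = nodes, edges = edges, barriers = bar,
                 graph = g, tree = tr),
            class = "river_network")
}

parse_barriers <- function(edges) {
  out <- list()
  for (i in seq_len(nrow(edges))) {
    s <- edges$barriers[i]
    if (is.na(s) || !nzchar(trimws(s))) next
    for (item in strsplit(s, ";")[[1]]) {
      f <- strsplit(trimws(item), ":")[[1]]
      if (length(f) < 2) stop("malformed barrier spec: '", item, "'")
      out[[length(out) + 1]] <- data.frame(
        edge_id = edges$edge_id[i], barrier_id = f[1], type = f[2],
        pos = if (length(f) >= 3) as.numeric(f[3]) else NA_real_)
    }
  }
  if (!length(out))
    return(data.frame(edge_id = character(), barrier_id = character(),
                      type = character(), pos = numeric()))
  do.call(rbind, out)
}

#' Read a river network from edge/node CSVs
#' @param edge_csv path to edge table (edge_id, from, to, length_km,
#'   barriers, loop)
#' @param node_csv path to node table (node_id, kind, site_id)
#' @return river_network
#' @export
read_river_network <- function(edge_csv, node_csv) {
  river_network(read.csv(node_csv, stringsAsFactors = FALSE),
                read.csv(edge_csv, stringsAsFactors = FALSE))
}

#' @export
print.river_network <- function(x, ...) {
  cat("river_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "sections,",
      nrow(x$barriers), "barriers\n")
  if (nrow(x$barriers))
    print(table(x$barriers$type))
  invisible(x)
}

node_of_site <- function(net, site) {
  i <- match(site, net$nodes$site_id)
  if (is.na(i)) {
    if (site %in% net$nodes$node_id) return(site)  # allow raw node ids
    stop("unknown site/node: ", site)
  }
  net$nodes$node_id[i]
}

## edge ids on the unique tree path between two nodes
path_edge_ids <- function(net, a, b) {
  if (a == b) return(character(0))
  p <- igraph::shortest_paths(net$tree, from = a, to = b, output = "epath")
  ep <- p$epath[[1]]
  if (length(ep) == 0) stop("nodes ", a, " and ", b, " are disconnected")
  igraph::E(net$tree)$edge_id[as.integer(ep)]
}

#' Waterway distance between two sites or nodes
#' @param net river_network
#' @param a,b site ids or node ids
#' @return distance in km along the unique tree path
#' @export
waterway_distance <- function(net, a, b) {
  na <- node_of_site(net, a); nb <- node_of_site(net, b)
  if (na == nb) return(0)
  eids <- path_edge_ids(net, na, nb)
  sum(net$edges$length_km[match(eids, net$edges$edge_id)])
}

#' Typed barrier counts between two sites or nodes
#' @inheritParams waterway_distance
#' @return named vector: one count per barrier type plus \code{TOTAL}
#' @export
barrier_counts <- function(net, a, b) {
  na <- node_of_site(net, a); nb <- node_of_site(net, b)
  cnt <- setNames(integer(length(BARRIER_TYPES)), BARRIER_TYPES)
  if (na != nb) {
    eids <- path_edge_ids(net, na, nb)
    onpath <- net$barriers[net$barriers$edge_id %in% eids, , drop = FALSE]
    tab <- table(factor(onpath$type, levels = BARRIER_TYPES))
    cnt[] <- as.integer(tab)
  }
  c(cnt, TOTAL = sum(cnt))
}

#' Pairwise waterway-distance and barrier-count tables
#'
#' @param net river_network
#' @param sites site ids defining row/column order
#' @return named list of \code{pairwise_table}s: \code{DISTANCE_KM},
#'   \code{BARRIERS_ALL} (all barriers incl. natural falls),
#'   \code{BARRIERS_FISHPASS}, \code{BARRIERS_NOFISHPASS} (man-made, no
#'   fishpass, falls excluded) and \code{RHINEFALLS} (indicator that a
#'   natural-falls barrier separates the pair)
#' @export
pairwise_river_tables <- function(net, sites) {
  ns <- length(sites)
  D <- FP <- NF <- FA <- matrix(0, ns, ns, dimnames = list(sites, sites))
  for (i in seq_len(ns - 1)) for (k in (i + 1):ns) {
    D[i, k] <- D[k, i] <- waterway_distance(net, sites[i], sites[k])
    cnt <- barrier_counts(net, sites[i], sites[k])
    FP[i, k] <- FP[k, i] <- cnt["FISHPASS"]
    NF[i, k] <- NF[k, i] <- cnt["NO_FISHPASS"]
    FA[i, k] <- FA[k, i] <- as.integer(cnt["NATURAL_FALLS"] > 0)
  }
  list(DISTANCE_KM = pairwise_table(D, "DISTANCE_KM", sites),
       BARRIERS_ALL = pairwise_table(FP + NF + FA, "BARRIERS_ALL", sites),
       BARRIERS_FISHPASS = pairwise_table(FP, "BARRIERS_FISHPASS", sites),
       BARRIERS_NOFISHPASS = pairwise_table(NF, "BARRIERS_NOFISHPASS", sites),
       RHINEFALLS = pairwise_table(FA, "RHINEFALLS", sites))
}

#' Upstream profile from a reference point
#'
#' Distance and typed barrier counts along the river from a downstream
#' reference node to each site, as used for models of allelic richness
#' against upstream position.
#'
#' @param net river_network
#' @param ref node id of the reference point (most downstream anchor)
#' @param sites site ids (default: all site nodes)
#' @return data.frame \code{site, distance_km, fishpass, no_fishpass,
#'   natural_falls, all_barriers}
#' @export
upstream_profile <- function(net, ref, sites = NULL) {
  if (!ref %in% net$nodes$node_id) stop("unknown reference node: ", ref)
  if (is.null(sites))
    sites <- net$nodes$site_id[net$nodes$kind == "site" & !is.na(net$nodes$site_id)]
  rows <- lapply(sites, function(s) {
    d <- waterway_distance(net, ref, s)
    cnt <- barrier_counts(net, ref, s)
    data.frame(site = s, distance_km = d,
               fishpass = cnt[["FISHPASS"]],
               no_fishpass = cnt[["NO_FISHPASS"]],
               natural_falls = cnt[["NATURAL_FALLS"]],
               all_barriers = cnt[["TOTAL"]])
  })
  do.call(rbind, rows)
}

#' Total barrier counts by type over the whole network
#' @param net river_network
#' @return named integer vector over barrier types
#' @export
barrier_totals <- function(net) {
  tab <- table(factor(net$barriers$type, levels = BARRIER_TYPES))
  setNames(as.integer(tab), BARRIER_TYPES)
}
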