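# Network- and node-level topology: global statistics, fast-greedy module
# detection, within-/among-module connectivity (Zi/Pi), keystone role
# classification, and top-degree hub subnetworks.
#
# Modularity, betweenness and shortest paths are undefined for negative
# edge weights, so all topology statistics run on the unweighted graph;
# the sign layer is retained for reporting only.

#' Convert an AssociationNetwork to an igraph graph
#'
#' @param net an [AssociationNetwork-class].
#' @param weighted keep signed weights as an edge attribute.
#' @return an undirected igraph graph containing every node (including
#'   isolated ones).
#' @export
asIgraph <- function(net, weighted = TRUE) {
  stopifnot(methods::is(net, "AssociationNetwork"))
  ed <- edges(net)
  g <- igraph::graph_from_data_frame(
    ed[, c("from", "to", if (weighted) "weight")],
    directed = FALSE,
    vertices = data.frame(name = net@nodes, domain = net@nodeDomain,
                          stringsAsFactors = FALSE))
  g
}

#' Global network statistics
#'
#' Edge density `2m / (n (n - 1))`, global transitivity (3 x triangles /
#' connected triples), module count and modularity from fast-greedy
#' detection, and the percentage of negative edges.
#'
#' @param net an [AssociationNetwork-class] with at least 2 nodes.
#' @return named list: `n_nodes`, `n_edges`, `edge_density`, `transitivity`,
#'   `n_modules`, `modularity`, `pct_negative_edges`.
#' @export
globalStats <- function(net) {
  stopifnot(methods::is(net, "AssociationNetwork"))
  n <- length(net@nodes)
  if (n < 2) stopf("need at least 2 nodes")
  ed <- edges(net)
  m <- nrow(ed)
  g <- asIgraph(net, weighted = FALSE)
  trans <- igraph::transitivity(g, type = "global")
  if (is.nan(trans)) trans <- 0
  part <- fastGreedyModules(net)
  if (m == 0) warnf("network has no edges; pct_negative_edges set to 0")
  list(n_nodes = n, n_edges = m,
       edge_density = 2 * m / (n * (n - 1)),
       transitivity = trans,
       n_modules = length(unique(part$membership)),
       modularity = part$modularity,
       pct_negative_edges = if (m == 0) 0 else 100 * mean(ed$sign == "negative"))
}

#' Fast-greedy module detection
#'
#' Greedy agglomerative modularity maximization (merging the community
#' pair with the largest modularity gain until no positive gain remains)
#' on the unweighted graph. Isolated nodes become singleton modules.
#' Modularity is `Q = sum_c (e_cc - a_c^2)` with `e_cc` the fraction of
#' edges inside module c and `a_c` the fraction of edge ends in c.
#'
#' @param net an [AssociationNetwork-class] or igraph graph.
#' @param useWeights `"none"` (default; the paper-level convention) or
#'   `"abs"` to optimize with absolute edge weights.
#' @return list of class `gutweb_module_partition`: `membership` (named
#'   integer), `modularity`, `method`.
#' @export
fastGreedyModules <- function(net, useWeights = c("none", "abs")) {
  useWeights <- match.arg(useWeights)
  g <- if (methods::is(net, "AssociationNetwork")) asIgraph(net) else net
  if (igraph::vcount(g) == 0)
    return(structure(list(membership = stats::setNames(integer(0), character(0)),
                          modularity = 0, method = "fast_greedy"),
                     class = "gutweb_module_partition"))
  if (igraph::ecount(g) == 0) {
    memb <- stats::setNames(seq_len(igraph::vcount(g)), igraph::V(g)$name)
    return(structure(list(membership = memb, modularity = 0,
                          method = "fast_greedy"),
                     class = "gutweb_module_partition"))
  }
  w <- if (useWeights == "abs" && "weight" %in% igraph::edge_attr_names(g))
    abs(igraph::E(g)$weight) else rep(1, igraph::ecount(g))
  cl <- igraph::cluster_fast_greedy(g, weights = w)
  # cut the dendrogram at the maximum-Q level ourselves; on ties keep the
  # coarser partition (a zero-gain merge is still taken by the greedy rule)
  nv <- igraph::vcount(g)
  ks <- seq(nv - nrow(cl$merges), nv)
  best_q <- -Inf; memb <- NULL
  for (k in ks) {
    mk <- igraph::cut_at(cl, no = k)
    qk <- igraph::modularity(g, mk, weights = w)
    if (qk > best_q + 1e-12) {
      best_q <- qk; memb <- mk
    }
  }
  memb <- stats::setNames(as.integer(memb), igraph::V(g)$name)
  Q <- best_q
  structure(list(membership = memb, modularity = Q, method = "fast_greedy"),
            class = "gutweb_module_partition")
}

#' @export
print.gutweb_module_partition <- function(x, ...) {
  cat(sprintf("Module partition (%s): %d modules over %d nodes, Q = %.4f\n",
              x$method, length(unique(x$membership)), length(x$membership),
              x$modularity))
  invisible(x)
}

#' Within-module degree z-score and among-module connectivity
#'
#' `zi = (k_within - mean(k_within over the node's module)) / sd(...)`,
#' defined as 0 when the module's within-degree sd is 0 (singleton modules
#' are peripherals by default). `pi = 1 - sum_c (k_ic / k_i)^2` over
#' modules c, and 0 for isolated nodes.
#'
#' @param net an [AssociationNetwork-class].
#' @param partition a partition from [fastGreedyModules()] (or a named
#'   membership vector covering all nodes).
#' @return data.frame: `node`, `module`, `degree`, `within_degree`, `zi`,
#'   `pi`.
#' @export
ziPi <- function(net, partition) {
  stopifnot(methods::is(net, "AssociationNetwork"))
  memb <- if (inherits(partition, "gutweb_module_partition"))
    partition$membership else partition
  if (!all(net@nodes %in% names(memb)))
    stopf("partition must cover all nodes")
  memb <- memb[net@nodes]
  g <- asIgraph(net, weighted = FALSE)
  n <- length(net@nodes)
  deg <- igraph::degree(g)[net@nodes]

  mods <- sort(unique(memb))
  # k_ic: links of node i into module c
  kic <- matrix(0, n, length(mods), dimnames = list(net@nodes, mods))
  ed <- edges(net)
  if (nrow(ed)) {
    for (r in seq_len(nrow(ed))) {
      kic[ed$from[r], as.character(memb[ed$to[r]])] <-
        kic[ed$from[r], as.character(memb[ed$to[r]])] + 1
      kic[ed$to[r], as.character(memb[ed$from[r]])] <-
        kic[ed$to[r], as.character(memb[ed$from[r]])] + 1
    }
  }
  within <- kic[cbind(seq_len(n), match(as.character(memb), colnames(kic)))]
  zi <- numeric(n)
  for (m in mods) {
    sel <- memb == m
    mu <- mean(within[sel])
    sdv <- stats::sd(within[sel])
    zi[sel] <- if (is.na(sdv) || sdv == 0) 0 else (within[sel] - mu) / sdv
  }
  pi <- ifelse(deg == 0, 0, 1 - rowSums((kic / pmax(deg, 1))^2))
  data.frame(node = net@nodes, module = as.integer(memb),
             degree = as.integer(deg), within_degree = as.integer(within),
             zi = zi, pi = pi, stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify nodes into keystone roles from the Zi-Pi plane
#'
#' network hub: `zi >= ziThreshold` and `pi > piThreshold`; module hub:
#' `zi >= ziThreshold` and `pi <= piThreshold`; connector: `zi <
#' ziThreshold` and `pi > piThreshold`; peripheral otherwise. The default
#' thresholds (2.5, 0.62) are the established convention for microbial
#' co-occurrence networks.
#'
#' @param profiles data.frame with `zi` and `pi` columns (from [ziPi()]).
#' @param ziThreshold,piThreshold classification thresholds.
#' @return the input data.frame with a `role` factor column added.
#' @export
classifyRoles <- function(profiles, ziThreshold = 2.5, piThreshold = 0.62) {
  stopifnot(all(c("zi", "pi") %in% names(profiles)))
  hi_z <- profiles$zi >= ziThreshold
  hi_p <- profiles$pi > piThreshold
  role <- ifelse(hi_z & hi_p, "network_hub",
          ifelse(hi_z, "module_hub",
          ifelse(hi_p, "connector", "peripheral")))
  profiles$role <- factor(role, levels = c("peripheral", "connector",
                                           "module_hub", "network_hub"))
  profiles
}

#' Per-node topology profile
#'
#' Degree, betweenness (shortest-path counting on the unweighted graph),
#' module membership, Zi/Pi and keystone role in one table.
#'
#' @param net an [AssociationNetwork-class].
#' @param partition optional partition; computed by [fastGreedyModules()]
#'   when NULL.
#' @param ziThreshold,piThreshold role thresholds, see [classifyRoles()].
#' @return data.frame, one row per node.
#' @export
nodeTopology <- function(net, partition = NULL, ziThreshold = 2.5,
                         piThreshold = 0.62) {
  if (is.null(partition)) partition <- fastGreedyModules(net)
  prof <- ziPi(net, partition)
  g <- asIgraph(net, weighted = FALSE)
  prof$betweenness <- unname(igraph::betweenness(g, weights = NA)[prof$node])
  prof <- prof[, c("node", "module", "degree", "within_degree",
                   "betweenness", "zi", "pi")]
  classifyRoles(prof, ziThreshold, piThreshold)
}

#' Induced subnetwork on the top-degree nodes
#'
#' Keeps the `ceiling(topFraction * n)` nodes of highest degree (ties
#' broken by betweenness, then by node id) and the edges among them.
#'
#' @param net an [AssociationNetwork-class].
#' @param topFraction fraction of nodes to keep (default 0.30).
#' @return an [AssociationNetwork-class] on the retained nodes; inference
#'   provenance is carried over.
#' @export
hubSubnetwork <- function(net, topFraction = 0.30) {
  stopifnot(methods::is(net, "AssociationNetwork"))
  if (topFraction <= 0 || topFraction > 1)
    stopf("topFraction must lie in (0, 1]")
  g <- asIgraph(net, weighted = FALSE)
  deg <- igraph::degree(g)[net@nodes]
  btw <- igraph::betweenness(g, weights = NA)[net@nodes]
  ord <- order(-deg, -btw, net@nodes, method = "radix")
  keep <- net@nodes[ord[seq_len(ceiling(topFraction * length(net@nodes)))]]
  ed <- edges(net)
  ed <- ed[ed$from %in% keep & ed$to %in% keep, , drop = FALSE]
  rownames(ed) <- NULL
  .new_network(nodes = keep,
               nodeDomain = net@nodeDomain[match(keep, net@nodes)],
               edgeTable = ed, lambdaPath = net@lambdaPath,
               selectedLambda = net@selectedLambda,
               instabilityPerLambda = net@instabilityPerLambda,
               subsampleCount = net@subsampleCount, seed = net@seed,
               signConflicts = net@signConflicts)
}
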