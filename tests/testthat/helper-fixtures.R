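# fixtures and independent oracles built in code

tiny_table <- function() {
  m <- matrix(c(0L, 2L, 8L,
                5L, 5L, 5L,
                1L, 0L, 3L), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("fA", "fB", "fC")))
  featureTable(m, c("16S", "16S", "ITS"), c("Bacteria", "Bacteria", "Fungi"))
}

# graph stub for simulateCounts with a given precision matrix
graph_stub <- function(precision) {
  ids <- sprintf("f%03d", seq_len(ncol(precision)))
  dimnames(precision) <- list(ids, ids)
  list(precision = precision,
       edges = data.frame(from = character(0), to = character(0)),
       modules = NULL, p = ncol(precision), topology = "custom")
}

random_metadata <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    host_group = rep(c("frog", "lizard", "salamander"), length.out = n),
    host_genus = "g", state = "TN", ecoregion3 = "eco1",
    dna_concentration = rlnorm(n, log(20), 0.6),
    is_ntc = FALSE, stringsAsFactors = FALSE
  )
}

# all set partitions of 1..n as membership vectors (restricted growth strings)
enum_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxblock) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (b in seq_len(maxblock + 1L)) {
      rec(c(prefix, b), max(maxblock, b))
    }
  }
  rec(integer(0), 0L)
  out
}

# modularity of an unweighted graph under a given membership vector,
# computed from first principles: Q = sum_c (e_cc - a_c^2)
modularity_oracle <- function(edge_i, edge_j, membership) {
  m <- length(edge_i)
  if (m == 0) return(0)
  ci <- membership[edge_i]; cj <- membership[edge_j]
  blocks <- sort(unique(membership))
  ecc <- vapply(blocks, function(b) sum(ci == b & cj == b) / m, numeric(1))
  ac <- vapply(blocks, function(b) (sum(ci == b) + sum(cj == b)) / (2 * m),
               numeric(1))
  sum(ecc - ac^2)
}

# exhaustive maximum modularity over all set partitions (n <= 8)
max_modularity_bruteforce <- function(edge_i, edge_j, n) {
  parts <- enum_partitions(n)
  max(vapply(parts, function(p) modularity_oracle(edge_i, edge_j, p),
             numeric(1)))
}

# brute-force IP from the 2x2 contingency table of two 0/1 vectors
ip_oracle <- function(ind, tgt) {
  ind <- ind > 0; tgt <- tgt > 0
  n1 <- sum(ind); n0 <- sum(!ind)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  a <- sum(ind & tgt) / n1
  b <- sum(!ind & !tgt) / n0
  sqrt(a * b)
}

# network for topology tests: one node wired into several modules plus
# star-shaped modules; returns net + a designed partition
designed_role_graph <- function() {
  # module 1: star around "hub1" with 14 leaves (a module hub)
  # module 2: star around "multi" with 12 leaves, plus "multi" linked to
  #           4 nodes in each of modules 3-5 (a network hub: high zi, high pi)
  # modules 3-5: 8-cycles (peripherals)
  ed <- list()
  leaves1 <- sprintf("m1L%02d", 1:14)
  ed$m1 <- data.frame(from = "hub1", to = leaves1)
  leaves2 <- sprintf("m2L%02d", 1:12)
  ed$m2 <- data.frame(from = "multi", to = leaves2)
  cyc <- function(pref) {
    v <- sprintf("%s%02d", pref, 1:8)
    data.frame(from = v, to = v[c(2:8, 1)])
  }
  ed$m3 <- cyc("m3N"); ed$m4 <- cyc("m4N"); ed$m5 <- cyc("m5N")
  ed$x3 <- data.frame(from = "multi", to = sprintf("m3N%02d", 1:4))
  ed$x4 <- data.frame(from = "multi", to = sprintf("m4N%02d", 1:4))
  ed$x5 <- data.frame(from = "multi", to = sprintf("m5N%02d", 1:4))
  edges <- do.call(rbind, ed)
  edges$weight <- 0.5
  net <- associationNetwork(edges)
  memb <- c(stats::setNames(rep(1L, 15), c("hub1", leaves1)),
            stats::setNames(rep(2L, 13), c("multi", leaves2)),
            stats::setNames(rep(3L, 8), sprintf("m3N%02d", 1:8)),
            stats::setNames(rep(4L, 8), sprintf("m4N%02d", 1:8)),
            stats::setNames(rep(5L, 8), sprintf("m5N%02d", 1:8)))
  list(net = net, membership = memb)
}
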