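test_that("global statistics match direct counts", {
  # complete graph K4
  pairs <- t(combn(letters[1:4], 2))
  k4 <- associationNetwork(data.frame(from = pairs[, 1], to = pairs[, 2],
                                      weight = 1))
  gs <- globalStats(k4)
  expect_equal(gs$edge_density, 1)
  expect_equal(gs$transitivity, 1)
  # path a-b-c: density 2*2/(3*2), no triangles
  path3 <- associationNetwork(data.frame(from = c("a", "b"), to = c("b", "c"),
                                         weight = 1))
  gs <- globalStats(path3)
  expect_equal(gs$edge_density, 2 / 3)
  expect_equal(gs$transitivity, 0)
  # one negative edge among 4
  net <- associationNetwork(data.frame(from = c("a", "b", "c", "d"),
                                       to = c("b", "c", "d", "e"),
                                       weight = c(1, 1, -1, 1)))
  expect_equal(globalStats(net)$pct_negative_edges, 25)
  expect_warning(gs0 <- globalStats(associationNetwork(
    data.frame(from = character(0), to = character(0), weight = numeric(0)),
    nodes = c("a", "b"))), "no edges")
  expect_equal(gs0$pct_negative_edges, 0)
})

test_that("fast-greedy modules recover planted structure with exact Q", {
  # two disconnected triangles: 2 modules, Q = 2 * (0.5 - 0.25) = 0.5
  tri <- function(v) data.frame(from = v, to = v[c(2, 3, 1)])
  net <- associationNetwork(within(rbind(tri(c("a", "b", "c")),
                                         tri(c("x", "y", "z"))),
                                   weight <- 1))
  part <- fastGreedyModules(net)
  expect_equal(length(unique(part$membership)), 2L)
  expect_equal(part$modularity, 0.5)
  expect_equal(length(unique(part$membership[c("a", "b", "c")])), 1L)
  # a single clique collapses to one module with Q = 0
  pairs <- t(combn(letters[1:5], 2))
  k5 <- associationNetwork(data.frame(from = pairs[, 1], to = pairs[, 2],
                                      weight = 1))
  part <- fastGreedyModules(k5)
  expect_equal(length(unique(part$membership)), 1L)
  expect_equal(part$modularity, 0)
  # isolated nodes become singleton modules
  net <- associationNetwork(data.frame(from = "a", to = "b", weight = 1),
                            nodes = c("a", "b", "c"))
  part <- fastGreedyModules(net)
  expect_equal(length(unique(part$membership)), 2L)
})

test_that("greedy modularity never beats the exhaustive optimum", {
  set.seed(11)
  n_eq <- 0L
  for (rep in 1:60) {
    n <- sample(4:8, 1)
    m <- sample(3:min(10, n * (n - 1) / 2), 1)
    pairs <- t(combn(n, 2))
    sel <- pairs[sample(nrow(pairs), m), , drop = FALSE]
    ids <- sprintf("n%02d", 1:n)
    net <- associationNetwork(data.frame(from = ids[sel[, 1]],
                                         to = ids[sel[, 2]], weight = 1),
                              nodes = ids)
    part <- fastGreedyModules(net)
    q_greedy <- part$modularity
    q_best <- max_modularity_bruteforce(sel[, 1], sel[, 2], n)
    expect_lte(q_greedy, q_best + 1e-12)
    # cross-check the reported Q against the from-scratch formula
    memb <- part$membership[ids]
    expect_equal(q_greedy, modularity_oracle(sel[, 1], sel[, 2], memb),
                 tolerance = 1e-12)
  }
  # equality on the two-clique family
  for (k in 3:5) {
    v1 <- sprintf("a%d", 1:k); v2 <- sprintf("b%d", 1:k)
    pairs <- rbind(t(combn(v1, 2)), t(combn(v2, 2)))
    net <- associationNetwork(data.frame(from = pairs[, 1], to = pairs[, 2],
                                         weight = 1))
    ids <- c(v1, v2)
    ei <- match(pairs[, 1], ids); ej <- match(pairs[, 2], ids)
    expect_equal(fastGreedyModules(net)$modularity,
                 max_modularity_bruteforce(ei, ej, 2 * k))
  }
})

test_that("zi/pi follow their formulas on designed graphs", {
  d <- designed_role_graph()
  prof <- ziPi(d$net, d$membership)
  rownames(prof) <- prof$node
  # all links inside the home module -> pi = 0
  expect_equal(prof["hub1", "pi"], 0)
  # hub1 dominates its star module
  expect_gt(prof["hub1", "zi"], 2.5)
  # multi: degree 24, 12 within, 4 links into each of three other modules
  expect_equal(prof["multi", "degree"], 24L)
  expect_equal(prof["multi", "pi"], 1 - ((12 / 24)^2 + 3 * (4 / 24)^2))
  # 2 links split across 2 modules -> pi = 0.5
  two <- associationNetwork(data.frame(from = c("v", "v"), to = c("p", "q"),
                                       weight = 1))
  memb <- c(v = 1L, p = 1L, q = 2L)
  pv <- ziPi(two, memb)
  expect_equal(pv$pi[pv$node == "v"], 0.5)
  # equal within-degrees give zi = 0 under the sd-zero rule
  cyc <- associationNetwork(data.frame(from = c("a", "b", "c"),
                                       to = c("b", "c", "a"), weight = 1))
  pc <- ziPi(cyc, c(a = 1L, b = 1L, c = 1L))
  expect_equal(pc$zi, rep(0, 3))
})

test_that("role classification partitions the zi/pi plane", {
  prof <- data.frame(zi = c(3.0, 0.0, 3.0, 1.0), pi = c(0.1, 0.8, 0.7, 0.3))
  roles <- classifyRoles(prof)$role
  expect_equal(as.character(roles),
               c("module_hub", "connector", "network_hub", "peripheral"))
  # designed graph: network hub, module hub and peripherals coexist
  d <- designed_role_graph()
  prof <- classifyRoles(ziPi(d$net, d$membership))
  rn <- prof$role[prof$node == "multi"]
  expect_equal(as.character(rn), "network_hub")
  expect_equal(as.character(prof$role[prof$node == "hub1"]), "module_hub")
  expect_equal(as.character(prof$role[prof$node == "m3N06"]), "peripheral")
  expect_false(any(is.na(prof$role)))
})

test_that("hub subnetworks keep the highest-degree nodes", {
  # star K1,9: the center always survives
  star <- associationNetwork(data.frame(from = "hub",
                                        to = sprintf("l%02d", 1:9),
                                        weight = 1))
  sub <- hubSubnetwork(star, 0.30)
  expect_equal(length(sub@nodes), 3L)
  expect_true("hub" %in% sub@nodes)
  # n = 10 -> ceiling(3) nodes retained
  expect_equal(length(sub@nodes), ceiling(0.3 * 10))
  # random graph agrees with a brute-force sort on (degree, betweenness, id)
  set.seed(21)
  pairs <- t(combn(30, 2))
  sel <- pairs[sample(nrow(pairs), 60), ]
  ids <- sprintf("n%02d", 1:30)
  net <- associationNetwork(data.frame(from = ids[sel[, 1]],
                                       to = ids[sel[, 2]], weight = 1),
                            nodes = ids)
  sub <- hubSubnetwork(net, 0.30)
  g <- asIgraph(net, weighted = FALSE)
  deg <- igraph::degree(g)[ids]
  btw <- igraph::betweenness(g, weights = NA)[ids]
  bf <- ids[order(-deg, -btw, ids, method = "radix")][1:9]
  expect_setequal(sub@nodes, bf)
})
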