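test_that("interaction graphs have the requested structure and are PD", {
  # band with 3 edges on 4 features -> tridiagonal support
  g <- makeInteractionGraph(4, "band", density = 0.49, seed = 1)
  expect_equal(nrow(g$edges), 3L)
  idx <- cbind(match(g$edges$from, colnames(g$precision)),
               match(g$edges$to, colnames(g$precision)))
  expect_true(all(abs(idx[, 1] - idx[, 2]) == 1))
  # support equals edges, signs consistent, Cholesky succeeds
  for (topo in c("modular", "band", "scale_free")) {
    g <- makeInteractionGraph(30, topo, nModules = 3, density = 0.08, seed = 2)
    expect_silent(chol(g$precision))
    off <- g$precision[upper.tri(g$precision)]
    expect_equal(sum(off != 0), nrow(g$edges))
    for (r in seq_len(nrow(g$edges))) {
      v <- g$precision[g$edges$from[r], g$edges$to[r]]
      expect_true(v != 0)
      expect_equal(g$edges$sign[r], if (v < 0) "positive" else "negative")
    }
  }
  # modular graphs concentrate edges within modules
  g <- makeInteractionGraph(60, "modular", nModules = 6,
                            density = 90 / choose(60, 2), seed = 3)
  within <- mean(g$modules[g$edges$from] == g$modules[g$edges$to])
  expect_gte(within, 0.95)
  expect_error(makeInteractionGraph(10, "modular", nModules = 5, density = 0.49),
               "infeasible")
})

test_that("simulated counts are deterministic and respect independence", {
  g <- makeInteractionGraph(20, "band", density = 0.06, seed = 1)
  a <- simulateCounts(g, 30, seed = 11)
  b <- simulateCounts(g, 30, seed = 11)
  expect_identical(counts(a$table), counts(b$table))
  expect_identical(a$metadata, b$metadata)
  expect_error(simulateCounts(g, 5), "nSamples")

  # zero-edge graph: clr correlations of random pairs stay near 0 (the
  # compositional closure from finite library depths leaves a small
  # negative residue concentrated on the most abundant features)
  g0 <- graph_stub(diag(40))
  sim <- simulateCounts(g0, 500, seed = 21)
  comp <- clrTransform(sim$table)
  set.seed(99)
  pairs <- replicate(20, sample(40, 2))
  rs <- apply(pairs, 2, function(pp) cor(comp[, pp[1]], comp[, pp[2]]))
  expect_lt(mean(abs(rs)), 0.05)
  expect_lt(max(abs(rs)), 0.2)
})

test_that("a strong positive partial correlation shows up in clr space", {
  # edge (1,2) with partial correlation 0.6 among otherwise independent
  # features (enough features that the clr row-centering cannot flip signs)
  P <- diag(10); P[1, 2] <- P[2, 1] <- -0.6
  g <- graph_stub(P)
  for (s in 1:5) {
    sim <- simulateCounts(g, 300, seed = 100 + s)
    comp <- clrTransform(sim$table)
    expect_gt(cor(comp[, 1], comp[, 2]), 0)
  }
})

test_that("planted contamination carries the 1/concentration signature", {
  g0 <- graph_stub(diag(50))
  sim <- simulateCounts(g0, 40, seed = 5)
  expect_error(addContamination(sim$table, sim$metadata, contamStrength = 0),
               "contamStrength")
  con <- addContamination(sim$table, sim$metadata, contaminantIds = 4,
                          contamStrength = 1, nNtc = 3, seed = 6)
  md <- con$metadata
  expect_true(all(md$is_ntc[md$host_group == "control"]))
  expect_true(all(md$host_group[md$is_ntc] == "control"))
  expect_equal(sum(md$is_ntc), 3L)
  # log frequency vs log concentration negatively correlated per contaminant
  cnt <- counts(con$table)[!md$is_ntc, ]
  conc <- md$dna_concentration[!md$is_ntc]
  lib <- rowSums(cnt)
  for (f in con$contaminantIds) {
    occ <- cnt[, f] > 0
    expect_lt(cor(log(cnt[occ, f] / lib[occ]), log(conc[occ])), 0)
  }
  # NTC libraries are dominated by the planted contaminants
  ntc <- counts(con$table)[md$is_ntc, , drop = FALSE]
  expect_gt(sum(ntc[, con$contaminantIds]) / sum(ntc), 0.8)
})

test_that("simulated trees are binary, seeded, and sized correctly", {
  tr <- simulateTree(3, seed = 1)
  expect_equal(length(tr$tip.label), 3L)
  expect_identical(ape::write.tree(simulateTree(12, seed = 4)),
                   ape::write.tree(simulateTree(12, seed = 4)))
  tr <- simulateTree(50, seed = 2)
  expect_equal(tr$Nnode, 49L)  # binary rooted tree: n - 1 internal nodes
  expect_true(all(tr$edge.length >= 0))
})

test_that("presets write the declared artifacts with truth on disk", {
  dir <- withr::local_tempdir()
  sim <- simulatePreset("contam", seed = 3, outDir = dir)
  expect_true(file.exists(file.path(dir, "counts.tsv")))
  expect_true(file.exists(file.path(dir, "metadata.tsv")))
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(sort(unlist(truth$contaminant_ids)),
               sort(sim$truth$contaminant_ids))
  back <- readFeatureTable(file.path(dir, "counts.tsv"))
  expect_identical(unname(counts(back)), unname(counts(sim$table)))
})
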