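test_that("Bray-Curtis matches the formula and its bounds", {
  m <- rbind(s1 = c(1, 2, 3), s2 = c(3, 2, 1), s3 = c(1, 2, 3),
             s4 = c(0, 0, 5))
  d <- as.matrix(brayCurtis(m))
  expect_equal(d["s1", "s2"], 4 / 12, tolerance = 1e-12)
  expect_equal(d["s1", "s3"], 0)
  expect_equal(d["s4", "s1"], (1 + 2 + 2) / (1 + 2 + 8))
  # disjoint supports give exactly 1
  dd <- as.matrix(brayCurtis(rbind(a = c(5, 0), b = c(0, 7))))
  expect_equal(dd["a", "b"], 1)
  expect_true(all(d >= 0 & d <= 1))
  expect_error(brayCurtis(rbind(c(1, 2), c(0, 0))), "zero-sum")
})

test_that("PCoA reconstructs Euclidean configurations", {
  set.seed(2)
  pts <- matrix(rnorm(8), 4, 2)
  d <- dist(pts)
  emb <- pcoa(d, k = 2)
  expect_equal(as.matrix(dist(emb$points)), as.matrix(d), tolerance = 1e-8)
  expect_true(all(emb$eigenvalues > -1e-8))
  # 2 points at distance d -> one axis at +-d/2
  e2 <- suppressWarnings(pcoa(dist(rbind(c(0, 0), c(3, 4))), k = 2))
  expect_equal(sort(as.numeric(e2$points[, 1])), c(-2.5, 2.5))
  expect_equal(ncol(e2$points), 1L)  # only one positive eigenvalue
})

test_that("dispersion homogeneity detects planted scale differences", {
  set.seed(5)
  # rigid translation: identical dispersions
  base <- matrix(rnorm(40), 20, 2)
  x <- rbind(base, sweep(base, 2, c(10, 10), "+"))
  groups <- rep(c("g1", "g2"), each = 20)
  bd <- betaDispersion(dist(x), groups, nPerm = 199, seed = 1)
  expect_equal(bd$F, 0, tolerance = 1e-6)
  # sigma ratio 5: the difference is detected in >= 95% of seeded runs
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    y <- rbind(matrix(rnorm(40, sd = 1), 20), matrix(rnorm(40, sd = 5), 20))
    bd <- betaDispersion(dist(y), groups, nPerm = 199, seed = s)
    if (bd$p <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
  expect_error(betaDispersion(dist(x), c("a", rep("b", 39))), "2 samples")
})

test_that("PERMANOVA agrees with adonis2 and a hand SS decomposition", {
  # 6-sample Euclidean toy, one factor with 3 + 3 samples
  x <- rbind(c(0, 0), c(1, 0), c(0, 1), c(5, 5), c(6, 5), c(5, 6))
  rownames(x) <- sprintf("s%d", 1:6)
  grp <- data.frame(g = factor(rep(c("a", "b"), each = 3)))
  d <- dist(x)
  pm <- permanova(d, ~ g, grp, nPerm = 99, seed = 1)
  tab <- pm$aov_table
  # hand decomposition: for Euclidean distances SS are the usual ANOVA SS
  centree <- function(m) sweep(m, 2, colMeans(m))
  ss_tot <- sum(centree(x)^2)
  ss_within <- sum(centree(x[1:3, ])^2) + sum(centree(x[4:6, ])^2)
  ss_between <- ss_tot - ss_within
  expect_equal(tab$SS[tab$term == "g"], ss_between, tolerance = 1e-10)
  expect_equal(tab$SS[tab$term == "Residual"], ss_within, tolerance = 1e-10)
  expect_equal(tab$F[1], (ss_between / 1) / (ss_within / 4), tolerance = 1e-10)
  expect_equal(sum(tab$R2[1:2]), 1)
  # cross-check F/SS/R2 against vegan's adonis2 on a crossed design
  set.seed(42)
  X <- matrix(rpois(30 * 20, 20), 30)
  meta <- data.frame(host = factor(rep(c("a", "b", "c"), each = 10)),
                     geo = factor(rep(c("x", "y"), 15)))
  db <- vegan::vegdist(X, "bray")
  ours <- permanova(db, ~ host * geo, meta, nPerm = 99, seed = 2)$aov_table
  ref <- as.data.frame(vegan::adonis2(db ~ host * geo, data = meta,
                                      permutations = 99, by = "terms"))
  expect_equal(ours$SS[1:3], ref$SumOfSqs[1:3], tolerance = 1e-10)
  expect_equal(ours$F[1:3], ref$F[1:3], tolerance = 1e-10)
  expect_equal(ours$df[1:4], ref$Df[1:4])
  expect_equal(ours$R2[1:3], ref$R2[1:3], tolerance = 1e-10)
})

test_that("permutation p matches full enumeration within Monte-Carlo error", {
  x <- rbind(c(0, 0), c(1, 1), c(0, 2), c(3, 2), c(4, 4), c(3, 5))
  rownames(x) <- sprintf("s%d", 1:6)
  grp <- data.frame(g = factor(rep(c("a", "b"), each = 3)))
  d <- dist(x)
  allp <- as.matrix(expand.grid(rep(list(1:6), 6)))
  allp <- allp[apply(allp, 1, function(r) length(unique(r)) == 6), ]
  exact <- permanova(d, ~ g, grp, permutations = allp)
  p_exact <- exact$aov_table$p[1]
  mc <- permanova(d, ~ g, grp, nPerm = 719, seed = 3)
  p_mc <- mc$aov_table$p[1]
  se <- sqrt(p_exact * (1 - p_exact) / 719)
  expect_lt(abs(p_mc - p_exact), 2 * se + 1 / 720)
  # identical multisets of profiles in both groups: F = 0, p = 1
  y <- rbind(x[1:3, ], x[1:3, ])
  rownames(y) <- sprintf("s%d", 1:6)
  pm0 <- permanova(dist(y), ~ g, grp, nPerm = 99, seed = 1)
  expect_equal(pm0$aov_table$F[1], 0, tolerance = 1e-10)
  expect_equal(pm0$aov_table$p[1], 1)
})

test_that("PERMANOVA is calibrated under the null and powered under effects", {
  # type-I error at alpha = 0.05 across null replicates
  set.seed(77)
  grp <- data.frame(g = factor(rep(c("a", "b", "c"), each = 10)))
  rej <- 0L
  nrep <- 200
  for (r in seq_len(nrep)) {
    X <- matrix(rpois(30 * 25, 15), 30)
    d <- vegan::vegdist(X, "bray")
    p <- permanova(d, ~ g, grp, nPerm = 199, seed = r)$aov_table$p[1]
    if (p <= 0.05) rej <- rej + 1L
  }
  expect_gte(rej / nrep, 0.02)
  expect_lte(rej / nrep, 0.08)
  # planted group effect (permanova preset): host effect detected
  hits <- 0L
  for (s in 1:10) {
    sim <- simulatePreset("permanova", seed = s)
    d <- brayCurtis(sim$table)
    p <- permanova(d, ~ host_group, sim$metadata, nPerm = 199,
                   seed = s)$aov_table$p[1]
    if (p <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("patristic distances sum branch lengths along tip paths", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:2);", path)
  d <- as.matrix(patristicMatrix(readTree(path)))
  expect_equal(d["A", "B"], 3)
  writeLines("((A:1,B:1):2,C:4);", path)
  d <- as.matrix(patristicMatrix(readTree(path)))
  expect_equal(d["A", "C"], 7)
  expect_equal(d["A", "B"], 2)
  # four-point condition holds on random trees
  for (s in 1:5) {
    tr <- simulateTree(8, seed = s)
    dm <- as.matrix(patristicMatrix(tr))
    tips <- rownames(dm)
    combs <- combn(tips, 4)
    for (k in seq_len(ncol(combs))) {
      q <- combs[, k]
      sums <- c(dm[q[1], q[2]] + dm[q[3], q[4]],
                dm[q[1], q[3]] + dm[q[2], q[4]],
                dm[q[1], q[4]] + dm[q[2], q[3]])
      two_max <- sort(sums, decreasing = TRUE)[1:2]
      expect_lt(abs(two_max[1] - two_max[2]), 1e-9)
    }
  }
})
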