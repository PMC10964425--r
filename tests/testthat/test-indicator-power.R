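test_that("indicator power matches hand contingency counting", {
  v <- c(1, 1, 1, 0, 0, 0)
  expect_equal(indicatorPower(v, v), 1)
  # 10 samples: indicator in 4 (target in 3 of those), absent in 6 (target
  # in 2): a = 3/4, b = 4/6, IP = sqrt(0.5)
  ind <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  tgt <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  expect_equal(indicatorPower(ind, tgt), sqrt(0.5), tolerance = 1e-12)
  expect_equal(round(indicatorPower(ind, tgt), 4), 0.7071)
  # ubiquitous target: b = 0 so IP = 0
  expect_equal(indicatorPower(ind, rep(1, 10)), 0)
  # undefined when the indicator is everywhere or nowhere
  expect_true(is.na(indicatorPower(rep(1, 10), tgt)))
  expect_true(is.na(indicatorPower(rep(0, 10), tgt)))
  expect_error(indicatorPower(1:3, 1:4), "equal length")
})

test_that("IP is invariant under joint complement (a/b swap)", {
  # enumerate every 2x2 contingency with n <= 12
  for (n in c(4, 8, 12)) {
    for (n11 in 0:n) for (n10 in 0:(n - n11)) for (n01 in 0:(n - n11 - n10)) {
      n00 <- n - n11 - n10 - n01
      ind <- c(rep(1, n11), rep(1, n10), rep(0, n01), rep(0, n00))
      tgt <- c(rep(1, n11), rep(0, n10), rep(1, n01), rep(0, n00))
      ip1 <- indicatorPower(ind, tgt)
      ip2 <- indicatorPower(1 - ind, 1 - tgt)
      if (is.na(ip1)) expect_true(is.na(ip2)) else expect_equal(ip1, ip2)
    }
  }
})

test_that("the vectorized IP matrix equals the per-pair oracle exactly", {
  set.seed(31)
  for (rep in 1:10) {
    I <- matrix(rbinom(40 * 12, 1, runif(1, 0.2, 0.8)), 40, 12)
    T <- matrix(rbinom(40 * 6, 1, runif(1, 0.2, 0.8)), 40, 6)
    ipm <- gutweb:::.ip_matrix(I, T)
    for (i in 1:12) for (j in 1:6) {
      o <- ip_oracle(I[, i], T[, j])
      if (is.na(o)) expect_true(is.na(ipm[i, j]))
      else expect_lt(abs(ipm[i, j] - o), 1e-12)
    }
  }
})

test_that("the full analysis filters, summarizes and orders correctly", {
  set.seed(7)
  n <- 30
  # block structure: targets co-occur with the first 5 indicators
  base <- rbinom(n, 1, 0.5)
  bact <- sapply(1:20, function(j) {
    if (j <= 5) ifelse(base == 1, rpois(n, 30), rbinom(n, 1, 0.1) * rpois(n, 5))
    else rbinom(n, 1, 0.6) * rpois(n, 12)
  })
  fungi <- sapply(1:4, function(j)
    ifelse(base == 1, rpois(n, 20), rbinom(n, 1, 0.1) * rpois(n, 3)))
  dimnames(bact) <- list(sprintf("s%02d", 1:n), sprintf("b%03d", 1:20))
  dimnames(fungi) <- list(sprintf("s%02d", 1:n), sprintf("f%03d", 1:4))
  bt <- featureTable(bact, "16S", "Bacteria")
  ft <- featureTable(fungi, "ITS", "Fungi")
  tax <- data.frame(feature_id = c(colnames(bact), colnames(fungi)),
                    class = c(rep(c("Clostridia", "Bacteroidia"), 10),
                              rep(NA, 4)),
                    genus = c(rep(NA, 20), rep("Basidiobolus", 4)))
  res <- indicatorAnalysis(bt, ft, taxonomy = tax, topN = 10,
                           targetMinReads = 10, minObservations = 10)
  expect_equal(dim(res$ip), c(10L, 4L))
  # summaries are means of the defined entries
  expect_equal(unname(res$tip_per_target),
               unname(colMeans(res$ip, na.rm = TRUE)))
  expect_equal(unname(res$mean_ip_per_indicator),
               unname(rowMeans(res$ip, na.rm = TRUE)))
  expect_true(all(res$mean_ip_per_class$n_indicators > 0))
  expect_setequal(res$row_order, seq_len(nrow(res$ip)))
  expect_setequal(res$col_order, seq_len(ncol(res$ip)))
  # block indicators predict the targets strongly
  blk <- rownames(res$ip) %in% sprintf("b%03d", 1:5)
  expect_gt(mean(res$ip[blk, ], na.rm = TRUE),
            mean(res$ip[!blk, ], na.rm = TRUE))
  # two indicators with IP 0.2 and 0.6 for one target -> TIP 0.4
  expect_equal(mean(c(0.2, 0.6)), 0.4)
})

test_that("correlation ordering follows complete-linkage agglomeration", {
  x <- seq_len(12)
  expect_equal(cor(x, 2 * x), 1)
  expect_equal(cor(x, -x), -1)
  # 4-point hand check: merge heights equal maxima of pairwise distances
  prof <- rbind(p1 = c(0, 0), p2 = c(1, 0), p3 = c(4, 0), p4 = c(4.5, 0))
  hc <- hclust(dist(prof), method = "complete")
  expect_equal(sort(hc$height), c(0.5, 1, 4.5))
  # heatmapOrder returns permutations and the Pearson matrix
  set.seed(12)
  A <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("i1", "i2", "i3")))
  B <- cbind(t1 = A[, 1] * 2 + rnorm(20, sd = .1), t2 = rnorm(20))
  hm <- heatmapOrder(A, B)
  expect_equal(dim(hm$correlation), c(3L, 2L))
  expect_gt(hm$correlation["i1", "t1"], 0.9)
  expect_setequal(hm$row_order, 1:3)
  # zero-variance vector: missing correlations, warning, clustering proceeds
  B2 <- cbind(B, t3 = rep(1, 20))
  expect_warning(hm2 <- heatmapOrder(A, B2), "zero-variance")
  expect_true(all(is.na(hm2$correlation[, "t3"])))
})
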