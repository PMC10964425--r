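# Distance-based community statistics: Bray-Curtis, PCoA, homogeneity of
# multivariate dispersion, PERMANOVA with crossed factors and interaction,
# and patristic distance matrices from trees.

#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum_j |x_j - y_j| / sum_j (x_j + y_j)`, values in \[0, 1\].
#'
#' @param table a [FeatureTable-class] or numeric matrix (samples x
#'   features) with positive row sums.
#' @return a `dist` object labelled by sample id.
#' @export
brayCurtis <- function(table) {
  if (methods::is(table, "FeatureTable")) table <- counts(table)
  if (any(rowSums(table) == 0))
    stopf("zero-sum sample rows: Bray-Curtis is undefined")
  vegan::vegdist(table, method = "bray")
}

#' Principal coordinate analysis of a distance matrix
#'
#' Double-centers `-0.5 * D^2` and eigendecomposes; coordinates are scaled
#' by the square root of their (positive) eigenvalues. Negative eigenvalues
#' (from non-Euclidean distances such as Bray-Curtis) are reported and
#' their axes omitted; when `k` exceeds the number of positive eigenvalues
#' fewer axes are returned with a warning.
#'
#' @param d a `dist` or symmetric matrix.
#' @param k number of axes requested.
#' @return list: `points` (n x k'), `eigenvalues` (all n), `negative`
#'   (the negative eigenvalues).
#' @export
pcoa <- function(d, k = 2) {
  if (k < 1) stopf("k must be >= 1")
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  cmd <- suppressWarnings(stats::cmdscale(d, k = min(k, n - 1), eig = TRUE))
  eig <- cmd$eig
  npos <- sum(eig > max(eig) * 1e-9)
  if (k > npos) {
    warnf("only %d positive eigenvalues; returning %d axes", npos, npos)
    k <- npos
  }
  pts <- cmd$points[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("PCo", seq_len(k))
  list(points = pts, eigenvalues = eig, negative = eig[eig < 0])
}

#' Homogeneity of multivariate dispersion across groups
#'
#' Embeds the distance matrix by PCoA, measures each sample's distance to
#' its group spatial median (or centroid) with negative-eigenvalue axes
#' subtracting their squared contributions (floored at 0), and tests
#' group differences with a one-way F on those distances, permuting group
#' labels. This is the classical multivariate dispersion test (vegan's
#' betadisper/permutest pair under the hood).
#'
#' @param d a `dist` or symmetric matrix.
#' @param groups factor-like group labels, every group with >= 2 samples.
#' @param center `"median"` (spatial median, default) or `"centroid"`.
#' @param nPerm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return list of class `gutweb_dispersion`: `distances` (per sample),
#'   `F`, `p`, `df`, `center`.
#' @export
betaDispersion <- function(d, groups, center = c("median", "centroid"),
                           nPerm = 999, seed = NULL) {
  center <- match.arg(center)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stopf("need at least 2 groups")
  if (any(table(groups) < 2)) stopf("every group needs at least 2 samples")
  d <- stats::as.dist(d)
  bd <- vegan::betadisper(d, groups, type = center)
  .set_seed_if(seed)
  pt <- vegan::permutest(bd, permutations = nPerm)
  tab <- pt$tab
  structure(list(distances = bd$distances,
                 F = tab$F[1], p = tab$`Pr(>F)`[1],
                 df = c(tab$Df[1], tab$Df[2]),
                 center = center, nPerm = nPerm, seed = seed),
            class = "gutweb_dispersion")
}

#' @export
print.gutweb_dispersion <- function(x, ...) {
  cat(sprintf("Multivariate dispersion (%s): F(%d, %d) = %.4f, P = %.4g (%d permutations)\n",
              x$center, x$df[1], x$df[2], x$F, x$p, x$nPerm))
  invisible(x)
}

# Gower-centered inner-product matrix of a distance matrix
#' @noRd
.gower_center <- function(D) {
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

# orthonormal bases of the cumulative (sequential) design, dropping
# aliased columns via rank-revealing QR; element k spans terms 1..k
#' @noRd
.sequential_bases <- function(formula, data) {
  mf <- stats::model.frame(formula, data, drop.unused.levels = TRUE)
  X <- stats::model.matrix(formula, mf)
  assign <- attr(X, "assign")
  labels <- attr(stats::terms(formula, data = data), "term.labels")
  Xc <- sweep(X[, assign != 0, drop = FALSE], 2,
              colMeans(X[, assign != 0, drop = FALSE]))
  assign <- assign[assign != 0]
  bases <- vector("list", length(labels))
  ranks <- integer(length(labels))
  for (k in seq_along(labels)) {
    Xk <- Xc[, assign <= k, drop = FALSE]
    qrk <- qr(Xk)
    r <- qrk$rank
    ranks[k] <- r
    bases[[k]] <- qr.Q(qrk)[, seq_len(r), drop = FALSE]
  }
  list(bases = bases, ranks = ranks, labels = labels)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the total sum of squared distances via the Gower-centered
#' inner-product matrix and hat matrices of the sequential
#' (order-of-entry) model, in the classical distance-based MANOVA
#' framework. Pseudo-F per term is `(SS_term / df_term) / (SS_resid /
#' df_resid)`; significance comes from free permutation of sample labels,
#' with the add-one estimator `p = (1 + #{F* >= F}) / (1 + nPerm)` so p
#' can never be exactly 0. Rank-deficient designs (empty factor cells) are
#' handled by dropping aliased columns; term df are rank increments.
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param formula right-hand-side formula over columns of `data`, e.g.
#'   `~ host_group * state` (sequential, in order of entry).
#' @param data data.frame of factors aligned with the rows of `d`.
#' @param nPerm number of permutations (default 999, so the smallest
#'   attainable p is 0.001).
#' @param seed integer seed for the permutation draws.
#' @param permutations optional explicit permutation matrix (rows =
#'   permutations of `1:n`); overrides `nPerm`, used e.g. for exact
#'   enumeration on small designs.
#' @return object of class `gutweb_permanova`: data.frame `aov_table` with
#'   one row per term plus Residual and Total (df, SS, F, R2, p).
#' @export
permanova <- function(d, formula, data, nPerm = 999, seed = NULL,
                      permutations = NULL) {
  D <- as.matrix(stats::as.dist(d))
  n <- nrow(D)
  if (nrow(data) != n) stopf("data rows must match the distance matrix")
  G <- .gower_center(D)
  sq <- .sequential_bases(formula, data)
  K <- length(sq$labels)
  if (!K) stopf("formula has no terms")

  tr_HG <- function(Q, M) sum(diag(crossprod(Q, M %*% Q)))
  ss_total <- sum(diag(G))
  fit_stats <- function(M) {
    cum <- vapply(sq$bases, tr_HG, numeric(1), M = M)
    ss <- diff(c(0, cum))
    ss_res <- sum(diag(M)) - cum[K]
    list(ss = ss, ss_res = ss_res)
  }
  df <- diff(c(0, sq$ranks))
  df_res <- n - 1 - sq$ranks[K]
  if (df_res <= 0) stopf("zero residual degrees of freedom: terms are confounded")
  obs <- fit_stats(G)
  Fobs <- (obs$ss / df) / (obs$ss_res / df_res)

  if (is.null(permutations)) {
    .set_seed_if(seed)
    permutations <- t(vapply(seq_len(nPerm), function(i) sample.int(n),
                             integer(n)))
  }
  nP <- nrow(permutations)
  exceed <- numeric(K)
  for (i in seq_len(nP)) {
    pp <- permutations[i, ]
    st <- fit_stats(G[pp, pp])
    Fp <- (st$ss / df) / (st$ss_res / df_res)
    exceed <- exceed + (Fp >= Fobs - 1e-12)
  }
  pval <- (1 + exceed) / (1 + nP)

  aov_table <- data.frame(
    term = c(sq$labels, "Residual", "Total"),
    df = c(df, df_res, n - 1),
    SS = c(obs$ss, obs$ss_res, ss_total),
    F = c(Fobs, NA, NA),
    R2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    p = c(pval, NA, NA),
    stringsAsFactors = FALSE
  )
  structure(list(aov_table = aov_table, nPerm = nP, seed = seed,
                 formula = formula),
            class = "gutweb_permanova")
}

#' @export
print.gutweb_permanova <- function(x, ...) {
  cat("PERMANOVA (sequential SS, free permutation of sample labels)\n")
  tab <- x$aov_table
  tab$SS <- signif(tab$SS, 5); tab$F <- signif(tab$F, 5)
  tab$R2 <- signif(tab$R2, 4)
  print(tab, row.names = FALSE)
  cat(sprintf("%d permutations\n", x$nPerm))
  invisible(x)
}

#' Patristic distance matrix from a tree
#'
#' `d(a, b)` is the sum of branch lengths along the unique path between
#' tips a and b.
#'
#' @param tree a `phylo` object with complete branch lengths and unique
#'   tip labels.
#' @return a `dist` labelled by tip.
#' @export
patristicMatrix <- function(tree) {
  validateTree(tree)
  stats::as.dist(stats::cophenetic(tree))
}
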