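# Sparse signed co-occurrence network inference from compositional counts:
# centered log-ratio transform, per-node L1-penalized neighborhood
# selection, and StARS stability selection over the lambda path.

#' Centered log-ratio transform of a count table
#'
#' For each sample row x, `y_j = log(x_j + pseudocount) - mean_k log(x_k +
#' pseudocount)`. Rows of the result sum to zero. The transform maps
#' compositions to unconstrained real space, where a Gaussian graphical
#' model is a sensible working model.
#'
#' @param table a [FeatureTable-class] or a numeric matrix
#'   (samples x features).
#' @param pseudocount positive value added before taking logs (default 1,
#'   the convention for count data; on all-positive data a pseudocount of 0
#'   makes the transform exactly scale-invariant).
#' @return numeric matrix (samples x features) with attribute
#'   `"pseudocount"`.
#' @export
clrTransform <- function(table, pseudocount = 1) {
  if (methods::is(table, "FeatureTable")) table <- counts(table)
  if (pseudocount < 0 || (pseudocount == 0 && any(table <= 0)))
    stopf("pseudocount must be > 0 unless all counts are positive")
  y <- log(table + pseudocount)
  y <- y - rowMeans(y)
  attr(y, "pseudocount") <- pseudocount
  y
}

# standardize columns to zero mean and unit variance (1/n denominator,
# matching the lasso's covariance scaling); constant columns become zero
#' @noRd
.std_n <- function(X) {
  X <- sweep(X, 2, colMeans(X))
  s <- sqrt(colMeans(X^2))
  s[s == 0] <- Inf
  sweep(X, 2, s, "/")
}

# per-node lasso regressions along a lambda path; returns, per lambda, the
# OR-symmetrized signed weighted adjacency and the count of sign conflicts
#' @noRd
.mb_path <- function(X, lambdas) {
  Xs <- .std_n(X)
  n <- nrow(Xs); p <- ncol(Xs); L <- length(lambdas)
  B <- array(0, c(p, p, L))
  for (j in seq_len(p)) {
    y <- Xs[, j]
    Xo <- Xs[, -j, drop = FALSE]
    if (ncol(Xo) == 1L) {
      cc <- sum(Xo[, 1] * y) / n
      beta <- vapply(lambdas, function(l) sign(cc) * max(abs(cc) - l, 0),
                     numeric(1))
      B[-j, j, ] <- matrix(beta, nrow = 1)
    } else {
      fit <- glmnet::glmnet(Xo, y, family = "gaussian", lambda = lambdas,
                            standardize = FALSE, intercept = FALSE)
      co <- as.matrix(fit$beta)
      if (ncol(co) < L) # glmnet stopped early; remaining lambdas keep last fit
        co <- cbind(co, co[, rep(ncol(co), L - ncol(co)), drop = FALSE])
      B[-j, j, ] <- co
    }
  }
  adj <- vector("list", L)
  conflicts <- integer(L)
  for (l in seq_len(L)) {
    A <- B[, , l]; At <- t(A)
    nz <- (A != 0) + (At != 0)
    W <- (A + At) / pmax(nz, 1)
    confl <- (A * At) < 0
    if (any(confl)) {
      pick <- ifelse(abs(A) >= abs(At), A, At)
      W[confl] <- pick[confl]
      conflicts[l] <- sum(confl[upper.tri(confl)])
    }
    dimnames(W) <- list(colnames(X), colnames(X))
    adj[[l]] <- W
  }
  list(adj = adj, conflicts = conflicts)
}

#' Lasso neighborhood selection at a single penalty
#'
#' Each feature is regressed on all others with an L1 penalty (columns
#' standardized to unit variance internally; the penalty applies to
#' standardized coefficients). An edge (i, j) exists when either directed
#' coefficient is nonzero (OR symmetrization); its weight is the mean of
#' the nonzero coefficients, or the larger-magnitude one when the two
#' disagree in sign (such conflicts are counted and reported via an
#' attribute).
#'
#' @param comp clr-transformed matrix from [clrTransform()].
#' @param lambda positive penalty; at `lambda >= max |cov|` between
#'   standardized columns the edge set is empty.
#' @return signed weighted adjacency matrix with attribute
#'   `"signConflicts"`.
#' @export
mbNeighborhood <- function(comp, lambda) {
  if (length(lambda) != 1 || lambda <= 0)
    stopf("lambda must be a single positive value (a dense lambda = 0 solution is not meaningful)")
  if (ncol(comp) < 2) stopf("need at least 2 features")
  res <- .mb_path(comp, lambda)
  W <- res$adj[[1]]
  attr(W, "signConflicts") <- res$conflicts[1]
  W
}

#' @noRd
.default_lambda_path <- function(comp, nLambda = 30, lambdaMinRatio = 0.01) {
  Xs <- .std_n(comp)
  C <- crossprod(Xs) / nrow(Xs)
  diag(C) <- 0
  lmax <- max(abs(C))
  if (lmax <= 0) stopf("degenerate composition matrix: no covariance")
  exp(seq(log(lmax), log(lmax * lambdaMinRatio), length.out = nLambda))
}

#' StARS stability selection of the co-occurrence network
#'
#' Draws `nSubsamples` subsamples of size `b = min(floor(10 sqrt(n)),
#' floor(0.8 n))` without replacement, runs neighborhood selection on each
#' at every lambda, and measures per-lambda edge instability as the mean of
#' `2 theta (1 - theta)` over all feature pairs, where theta is an edge's
#' selection frequency. Instability is monotonized from the sparse end
#' (running supremum as lambda decreases) and the smallest lambda - the
#' densest model - whose monotonized instability stays within `betaTarget`
#' is selected; the final network is refit on the full data at that lambda.
#' If no lambda meets the target, the lambda with instability closest to it
#' is used, with a warning.
#'
#' @param comp clr matrix from [clrTransform()].
#' @param lambdaPath strictly decreasing positive path; by default 30
#'   log-spaced values from the maximum absolute covariance down to 1% of
#'   it.
#' @param betaTarget instability target (default 0.05).
#' @param nSubsamples number of subsamples (>= 2; default 20).
#' @param seed integer seed governing the subsample draws.
#' @param nodeDomain optional named domain labels for the features.
#' @param nLambda,lambdaMinRatio path shape when `lambdaPath` is NULL.
#' @return an [AssociationNetwork-class].
#' @export
starsSelect <- function(comp, lambdaPath = NULL, betaTarget = 0.05,
                        nSubsamples = 20, seed = 1, nodeDomain = NULL,
                        nLambda = 30, lambdaMinRatio = 0.01) {
  n <- nrow(comp); p <- ncol(comp)
  if (nSubsamples < 2) stopf("nSubsamples must be >= 2")
  if (is.null(lambdaPath))
    lambdaPath <- .default_lambda_path(comp, nLambda, lambdaMinRatio)
  if (length(lambdaPath) > 1 && any(diff(lambdaPath) >= 0))
    stopf("lambdaPath must be strictly decreasing")
  if (any(lambdaPath <= 0)) stopf("lambdaPath must be positive")
  L <- length(lambdaPath)
  b <- min(floor(10 * sqrt(n)), floor(0.8 * n))
  b <- max(b, 3L)
  .set_seed_if(seed)
  sel_count <- array(0, c(p, p, L))
  for (s in seq_len(nSubsamples)) {
    idx <- sample.int(n, b)
    sub <- .mb_path(comp[idx, , drop = FALSE], lambdaPath)
    for (l in seq_len(L)) sel_count[, , l] <- sel_count[, , l] + (sub$adj[[l]] != 0)
  }
  ut <- upper.tri(matrix(0, p, p))
  nPairs <- sum(ut)
  instability <- vapply(seq_len(L), function(l) {
    theta <- sel_count[, , l][ut] / nSubsamples
    sum(2 * theta * (1 - theta)) / nPairs
  }, numeric(1))
  mono <- cummax(instability)
  ok <- which(mono <= betaTarget)
  if (length(ok)) {
    sel_idx <- max(ok)
  } else {
    sel_idx <- which.min(abs(instability - betaTarget))
    warnf("no lambda met the instability target %.3f; using the closest (%.4f)",
          betaTarget, instability[sel_idx])
  }

  full <- .mb_path(comp, lambdaPath)
  W <- full$adj[[sel_idx]]
  ed <- which(ut & W != 0, arr.ind = TRUE)
  ids <- colnames(comp)
  if (is.null(ids)) ids <- sprintf("f%03d", seq_len(p))
  edgeTable <- data.frame(
    from = ids[ed[, 1]], to = ids[ed[, 2]],
    weight = W[ed],
    sign = ifelse(W[ed] > 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  if (!is.null(nodeDomain)) nodeDomain <- unname(nodeDomain[ids])
  .new_network(nodes = ids, nodeDomain = nodeDomain, edgeTable = edgeTable,
               lambdaPath = lambdaPath, selectedLambda = lambdaPath[sel_idx],
               instabilityPerLambda = instability,
               subsampleCount = nSubsamples, seed = seed,
               signConflicts = full$conflicts[sel_idx])
}

#' Infer a co-occurrence network from a count table
#'
#' Convenience wrapper: [clrTransform()] then [starsSelect()], carrying the
#' table's feature domain labels onto the network nodes.
#'
#' @param table a [FeatureTable-class].
#' @param pseudocount clr pseudocount.
#' @param ... passed to [starsSelect()].
#' @return an [AssociationNetwork-class].
#' @export
inferNetwork <- function(table, pseudocount = 1, ...) {
  stopifnot(methods::is(table, "FeatureTable"))
  comp <- clrTransform(table, pseudocount)
  starsSelect(comp, nodeDomain = featureDomain(table), ...)
}
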