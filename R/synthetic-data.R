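# Synthetic multi-kingdom amplicon data with known ground truth.
#
# The generator plants (a) a sparse signed interaction graph realized as a
# positive-definite precision matrix, (b) reagent contaminants whose
# frequency varies inversely with sample DNA concentration plus no-template
# control libraries, and (c) multiplicative host-group effects, so every
# downstream stage has a recoverable target.

#' Generate a sparse signed interaction graph with a positive-definite
#' precision matrix
#'
#' Off-diagonal support of the precision matrix equals the graph edges;
#' positive definiteness is enforced by diagonal boosting. The association
#' sign of an edge is the sign of its partial correlation, i.e. minus the
#' sign of the precision entry.
#'
#' @param p number of features (>= 4).
#' @param topology `"modular"`, `"band"`, or `"scale_free"`.
#' @param nModules module count for the modular topology.
#' @param density target edge density in (0, 0.5); the edge count is
#'   `round(density * p * (p - 1) / 2)`.
#' @param positiveFraction fraction of edges with positive association
#'   (microbial co-occurrence networks are dominated by positive edges).
#' @param magnitudeRange range of |precision| entries for edges. After
#'   diagonal boosting the realized partial correlations land around
#'   0.2-0.4, a moderate-to-strong planted interaction.
#' @param maxDegree within-module degree cap for the modular topology
#'   (relaxed automatically when the requested density cannot be reached
#'   under it). Near-regular wiring keeps the planted partial correlations
#'   uniformly identifiable instead of being diluted by hub nodes through
#'   the positive-definiteness constraint.
#' @param seed integer seed.
#' @return list with elements `edges` (data.frame from, to, sign,
#'   partial_cor), `precision` (p x p matrix), `modules` (module id per
#'   feature; NA for non-modular topologies), `p`, `topology`.
#' @examples
#' g <- makeInteractionGraph(20, "band", density = 0.05, seed = 1)
#' nrow(g$edges)
#' @export
makeInteractionGraph <- function(p, topology = c("modular", "band", "scale_free"),
                                 nModules = 6, density = 0.05,
                                 positiveFraction = 0.9,
                                 magnitudeRange = c(0.4, 1.0),
                                 maxDegree = 3, seed = NULL) {
  topology <- match.arg(topology)
  if (p < 4) stopf("p must be >= 4")
  if (density <= 0 || density >= 0.5) stopf("density must lie in (0, 0.5)")
  .set_seed_if(seed)
  nPairs <- p * (p - 1) / 2
  target <- max(1L, round(density * nPairs))
  modules <- rep(NA_integer_, p)

  if (topology == "band") {
    # fill diagonals band by band until the target edge count is reached
    ii <- jj <- integer(0)
    for (k in seq_len(p - 1)) {
      add <- p - k
      take <- min(add, target - length(ii))
      if (take <= 0) break
      ii <- c(ii, seq_len(take))
      jj <- c(jj, seq_len(take) + k)
    }
    from <- ii; to <- jj
  } else if (topology == "modular") {
    modules <- rep(seq_len(nModules), length.out = p)
    within <- which(outer(modules, modules, "==") & upper.tri(diag(p)), arr.ind = TRUE)
    nBetween <- min(floor(0.03 * target), nPairs - nrow(within))
    nWithin <- target - nBetween
    if (nWithin > nrow(within))
      stopf("density %.3f infeasible for %d modules over %d features", density,
            nModules, p)
    deg <- integer(p)
    pick_capped <- function(pairs, ntake) {
      pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
      sel <- integer(0)
      cap <- maxDegree
      while (length(sel) < ntake && cap < p) {
        for (r in seq_len(nrow(pairs))) {
          if (length(sel) == ntake) break
          if (r %in% sel) next
          i <- pairs[r, 1]; j <- pairs[r, 2]
          if (deg[i] < cap && deg[j] < cap) {
            sel <- c(sel, r)
            deg[i] <<- deg[i] + 1L; deg[j] <<- deg[j] + 1L
          }
        }
        cap <- cap + 1L  # relax the cap if density is unreachable under it
      }
      pairs[sel, , drop = FALSE]
    }
    wsel <- pick_capped(within, nWithin)
    from <- wsel[, 1]; to <- wsel[, 2]
    if (nBetween > 0) {
      between <- which(outer(modules, modules, "!=") & upper.tri(diag(p)),
                       arr.ind = TRUE)
      bsel <- pick_capped(between, nBetween)
      from <- c(from, bsel[, 1]); to <- c(to, bsel[, 2])
    }
  } else { # scale_free
    m <- max(1L, round(target / p))
    g <- igraph::sample_pa(p, m = m, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    el <- el[el[, 1] != el[, 2], , drop = FALSE]
    el <- unique(cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
    from <- el[, 1]; to <- el[, 2]
  }

  nE <- length(from)
  sgn <- ifelse(stats::runif(nE) < positiveFraction, 1, -1)
  mag <- stats::runif(nE, magnitudeRange[1], magnitudeRange[2])
  # positive association  <=>  negative precision off-diagonal
  prec_val <- -sgn * mag

  Omega <- matrix(0, p, p)
  idx <- cbind(from, to)
  Omega[idx] <- prec_val
  Omega[idx[, 2:1, drop = FALSE]] <- prec_val
  ev_min <- min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values)
  d <- abs(ev_min) + 0.2
  diag(Omega) <- d

  ids <- sprintf("f%03d", seq_len(p))
  dimnames(Omega) <- list(ids, ids)
  edges <- data.frame(from = ids[from], to = ids[to],
                      sign = ifelse(sgn > 0, "positive", "negative"),
                      partial_cor = -prec_val / d,
                      stringsAsFactors = FALSE)
  list(edges = edges, precision = Omega,
       modules = stats::setNames(modules, ids), p = p, topology = topology)
}

# per-feature zero-inflated negative binomial quantile function
#' @noRd
.qzinb <- function(u, mu, size, zi) {
  out <- numeric(length(u))
  pos <- u > zi
  out[pos] <- stats::qnbinom((u[pos] - zi) / (1 - zi), mu = mu, size = size)
  out
}

#' Simulate multi-kingdom counts from a planted interaction graph
#'
#' Normal-to-anything construction: a latent multivariate normal with
#' covariance equal to the inverse precision matrix is pushed through each
#' feature's zero-inflated negative binomial quantile function; rows are
#' then resampled to stochastic library depths around `depthMean`, which
#' imposes the compositional constraint of real amplicon libraries.
#'
#' @param graph output of [makeInteractionGraph()].
#' @param nSamples number of samples (>= 10).
#' @param depthMean mean library depth.
#' @param zinb list of marginal parameters: `meanlog`/`sdlog` for the
#'   log-normal grid of feature means, `size` (dispersion) and `zero`
#'   (zero-inflation probability). Defaults: meanlog = log(20), sdlog = 1,
#'   size = 0.5, zero = 0.3.
#' @param markerSplit fraction of features tagged `16S` (domain Bacteria);
#'   the rest are `ITS` (Fungi).
#' @param groupEffect optional planted host-group effect: list with
#'   `features` (named list, host group -> feature ids) and `multiplier`
#'   (>= 1); affected features have their expected abundance multiplied in
#'   samples of that group.
#' @param hostGroups host groups to assign (recycled over samples).
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `table` (a [FeatureTable-class]) and `metadata`
#'   (validated sample metadata with log-normal DNA concentrations).
#' @export
simulateCounts <- function(graph, nSamples, depthMean = 10000,
                           zinb = list(), markerSplit = 0.5,
                           groupEffect = NULL,
                           hostGroups = c("frog", "lizard", "salamander"),
                           seed = NULL) {
  if (nSamples < 10) stopf("nSamples must be >= 10")
  zp <- utils::modifyList(list(meanlog = log(20), sdlog = 1, size = 0.5,
                               zero = 0.3), zinb)
  .set_seed_if(seed)
  Omega <- graph$precision
  p <- ncol(Omega)
  ch <- tryCatch(chol(Omega), error = function(e)
    stopf("precision matrix is not positive definite"))
  Sigma <- chol2inv(ch)
  R <- stats::cov2cor(Sigma)
  Z <- matrix(stats::rnorm(nSamples * p), nSamples, p) %*% chol(R)
  U <- stats::pnorm(Z)

  mu <- stats::rlnorm(p, meanlog = zp$meanlog, sdlog = zp$sdlog)
  raw <- matrix(0, nSamples, p)
  for (j in seq_len(p)) raw[, j] <- .qzinb(U[, j], mu[j], zp$size, zp$zero)

  ids <- colnames(Omega)
  groups <- rep(hostGroups, length.out = nSamples)
  if (!is.null(groupEffect)) {
    for (g in names(groupEffect$features)) {
      f <- match(groupEffect$features[[g]], ids)
      raw[groups == g, f] <- raw[groups == g, f] * groupEffect$multiplier
    }
  }

  depths <- pmax(1L, round(stats::rlnorm(nSamples, log(depthMean), 0.2)))
  cnt <- matrix(0, nSamples, p, dimnames = list(sprintf("s%03d", seq_len(nSamples)), ids))
  for (s in seq_len(nSamples)) {
    if (sum(raw[s, ]) > 0)
      cnt[s, ] <- stats::rmultinom(1, depths[s], prob = raw[s, ])
  }

  n16 <- round(markerSplit * p)
  marker <- c(rep("16S", n16), rep("ITS", p - n16))
  domain <- c(rep("Bacteria", n16), rep("Fungi", p - n16))
  table <- featureTable(cnt, marker, domain)

  metadata <- data.frame(
    sample_id = rownames(cnt),
    host_group = groups,
    host_genus = paste0("genus_", groups),
    state = rep(c("TN", "NC", "OH", "AZ"), length.out = nSamples),
    ecoregion3 = rep(sprintf("eco%02d", 1:4), length.out = nSamples),
    dna_concentration = stats::rlnorm(nSamples, log(20), 0.6),
    is_ntc = FALSE,
    stringsAsFactors = FALSE
  )
  validateSampleMetadata(metadata)
  list(table = table, metadata = metadata)
}

#' Plant reagent contaminants and append no-template control libraries
#'
#' The chosen features become reagent-derived: their counts are replaced by
#' Poisson draws with expectation `c * depth / dna_concentration` (c scaled
#' so a strength-1 contaminant carries about 0.5% of a median-concentration
#' library), reproducing the inverse frequency/concentration signature of
#' reagent contamination. Appended NTC libraries consist of the
#' contaminants plus a low rate of cross-talk noise.
#'
#' @param table a [FeatureTable-class].
#' @param metadata matching sample metadata.
#' @param contaminantIds feature ids to contaminate, or an integer count
#'   (features are then drawn at random).
#' @param contamStrength positive scale of the contamination signal.
#' @param nNtc number of NTC libraries to append.
#' @param ntcDepthMean mean NTC library size.
#' @param ntcNoiseRate fraction of NTC reads landing on non-contaminants.
#' @param seed integer seed.
#' @return list with `table`, `metadata` (NTC rows appended) and
#'   `contaminantIds`.
#' @export
addContamination <- function(table, metadata, contaminantIds = 5,
                             contamStrength = 1, nNtc = 3,
                             ntcDepthMean = 2000, ntcNoiseRate = 0.05,
                             seed = NULL) {
  stopifnot(methods::is(table, "FeatureTable"))
  if (contamStrength <= 0) stopf("contamStrength must be > 0")
  validateSampleMetadata(metadata)
  if (!all(metadata$sample_id == sampleNames(table)))
    stopf("metadata sample ids must match the table")
  .set_seed_if(seed)
  cnt <- counts(table)
  ids <- colnames(cnt)
  if (is.numeric(contaminantIds) && length(contaminantIds) == 1L)
    contaminantIds <- sample(ids, contaminantIds)
  if (!all(contaminantIds %in% ids)) stopf("unknown contaminant feature ids")

  conc <- metadata$dna_concentration
  depths <- rowSums(cnt)
  cc <- contamStrength * 0.005 * stats::median(conc)
  lam <- outer(cc * depths / conc, rep(1, length(contaminantIds)))
  cnt[, contaminantIds] <- matrix(stats::rpois(length(lam), lam), nrow(cnt))

  # NTC libraries: contaminants + low-rate noise on random other features
  ntc_cnt <- matrix(0, nNtc, ncol(cnt),
                    dimnames = list(sprintf("NTC%02d", seq_len(nNtc)), ids))
  ci <- match(contaminantIds, ids)
  for (s in seq_len(nNtc)) {
    d <- max(1L, stats::rpois(1, ntcDepthMean))
    prob <- rep(0, ncol(cnt))
    prob[ci] <- (1 - ntcNoiseRate) / length(ci)
    noise_f <- sample(setdiff(seq_len(ncol(cnt)), ci),
                      min(10L, ncol(cnt) - length(ci)))
    prob[noise_f] <- ntcNoiseRate / length(noise_f)
    ntc_cnt[s, ] <- stats::rmultinom(1, d, prob = prob)
  }
  out_cnt <- rbind(cnt, ntc_cnt)
  out_table <- featureTable(out_cnt, unname(featureMarker(table)),
                            unname(featureDomain(table)))
  ntc_meta <- data.frame(
    sample_id = rownames(ntc_cnt), host_group = "control",
    host_genus = "none", state = "none", ecoregion3 = "none",
    dna_concentration = NA_real_, is_ntc = TRUE, stringsAsFactors = FALSE
  )
  out_meta <- rbind(metadata, ntc_meta)
  validateSampleMetadata(out_meta)
  list(table = out_table, metadata = out_meta,
       contaminantIds = sort(contaminantIds))
}

#' Simulate a random tree with branch lengths
#'
#' Random binary (pure-birth style) topology with independent
#' exponential branch lengths; ultrametricity is deliberately not
#' enforced, matching trees estimated from marker-gene alignments.
#'
#' @param nTips number of tips (>= 3).
#' @param birthRate rate of the exponential branch-length distribution.
#' @param seed integer seed; the same seed reproduces the same newick.
#' @return a `phylo` object with `nTips` tips.
#' @export
simulateTree <- function(nTips, birthRate = 1, seed = NULL) {
  if (nTips < 3) stopf("nTips must be >= 3")
  .set_seed_if(seed)
  tree <- ape::rtree(nTips, rooted = TRUE,
                     br = function(n) stats::rexp(n, rate = birthRate))
  tree$tip.label <- sprintf("t%03d", seq_len(nTips))
  validateTree(tree)
  tree
}

#' Generate a preset synthetic study with ground truth
#'
#' Presets bundle the generator into the standing study conditions used
#' throughout the package's tests:
#' \describe{
#'   \item{network}{60 features, modular graph (6 modules, ~90 edges),
#'     150 samples, depth 10,000.}
#'   \item{contam}{100 independent features, 40 samples, 5 planted
#'     contaminants (strength 1) and 4 NTC libraries.}
#'   \item{permanova}{50 features, 30 samples in 3 host groups, effect
#'     multiplier 3 on a disjoint 10% feature block per group.}
#'   \item{tree}{a 50-tip random tree.}
#' }
#'
#' @param preset one of `"network"`, `"contam"`, `"permanova"`, `"tree"`.
#' @param seed integer seed.
#' @param outDir optional directory: when given, tables/newick are written
#'   in the package's TSV formats together with a `truth.yaml`.
#' @return list with the generated artifacts and a `truth` list (planted
#'   graph edges, contaminant ids, group effects, seed).
#' @export
simulatePreset <- function(preset = c("network", "contam", "permanova", "tree"),
                           seed = 1, outDir = NULL) {
  preset <- match.arg(preset)
  res <- switch(preset,
    network = {
      g <- makeInteractionGraph(60, "modular", nModules = 6,
                                density = 90 / choose(60, 2),
                                seed = deriveSeed(seed, "graph"))
      sim <- simulateCounts(g, nSamples = 150, depthMean = 10000,
                            seed = deriveSeed(seed, "counts"))
      c(sim, list(truth = list(preset = preset, seed = seed, edges = g$edges,
                               modules = g$modules), graph = g))
    },
    contam = {
      g <- makeInteractionGraph(100, "band", density = 1 / choose(100, 2),
                                seed = deriveSeed(seed, "graph"))
      sim <- simulateCounts(g, nSamples = 40, depthMean = 10000,
                            seed = deriveSeed(seed, "counts"))
      con <- addContamination(sim$table, sim$metadata, contaminantIds = 5,
                              contamStrength = 1, nNtc = 4,
                              seed = deriveSeed(seed, "contam"))
      list(table = con$table, metadata = con$metadata,
           truth = list(preset = preset, seed = seed,
                        contaminant_ids = con$contaminantIds))
    },
    permanova = {
      g <- makeInteractionGraph(50, "band", density = 1 / choose(50, 2),
                                seed = deriveSeed(seed, "graph"))
      ids <- colnames(g$precision)
      eff <- list(features = list(frog = ids[1:5], lizard = ids[6:10],
                                  salamander = ids[11:15]),
                  multiplier = 3)
      # moderate replicate-level noise so the planted host effect is the
      # dominant structure, as in rarefied field data where host explains
      # a stable share of community variance
      sim <- simulateCounts(g, nSamples = 30, depthMean = 10000,
                            zinb = list(size = 2, zero = 0.15),
                            groupEffect = eff,
                            hostGroups = c("frog", "lizard", "salamander"),
                            seed = deriveSeed(seed, "counts"))
      c(sim, list(truth = list(preset = preset, seed = seed, group_effect = eff)))
    },
    tree = {
      tr <- simulateTree(50, birthRate = 1, seed = deriveSeed(seed, "tree"))
      list(tree = tr, truth = list(preset = preset, seed = seed))
    }
  )
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$table))
      writeFeatureTable(res$table, file.path(outDir, "counts.tsv"))
    if (!is.null(res$metadata))
      writeSampleMetadata(res$metadata, file.path(outDir, "metadata.tsv"))
    if (!is.null(res$tree))
      writeTree(res$tree, file.path(outDir, "tree.nwk"))
    yaml::write_yaml(res$truth, file.path(outDir, "truth.yaml"))
  }
  res
}
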