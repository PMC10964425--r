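# Indicator power: how well the presence/absence of one taxon (typically a
# bacterial OTU) predicts the presence/absence of a target taxon (typically
# a Basidiobolus OTU). IP combines positive predictive power a = P(target
# present | indicator present) and negative predictive power b = P(target
# absent | indicator absent) as sqrt(a * b).

#' Indicator power of one presence/absence vector for another
#'
#' `IP = sqrt(a * b)` with `a` and `b` estimated from the 2x2 contingency
#' table of the two vectors. Undefined (NA) when the indicator is present
#' in all samples or in none (one conditional has an empty denominator).
#' A target present in every sample gives `b = 0`, hence IP = 0: ubiquitous
#' targets carry no negative indication.
#'
#' @param indicator,target logical/0-1 vectors of equal length (counts are
#'   binarized as `> 0`).
#' @return a value in \[0, 1\], or NA.
#' @examples
#' # indicator present in 4 of 10 samples (3 with the target), absent in 6
#' # (2 with the target): a = 3/4, b = 4/6, IP = sqrt(0.5)
#' ind <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
#' tgt <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
#' indicatorPower(ind, tgt)
#' @export
indicatorPower <- function(indicator, target) {
  if (length(indicator) != length(target))
    stopf("indicator and target must have equal length")
  if (!length(indicator)) stopf("vectors must be non-empty")
  ip <- as.numeric(indicator) > 0
  tp <- as.numeric(target) > 0
  n1 <- sum(ip); n0 <- sum(!ip)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  a <- sum(ip & tp) / n1
  b <- sum(!ip & !tp) / n0
  sqrt(a * b)
}

# vectorized IP over binary matrices (samples x indicators, samples x targets)
#' @noRd
.ip_matrix <- function(ind, tgt) {
  ind <- (ind > 0) * 1; tgt <- (tgt > 0) * 1
  n <- nrow(ind)
  n1 <- colSums(ind)
  n11 <- crossprod(ind, tgt)          # indicators x targets
  n00 <- crossprod(1 - ind, 1 - tgt)
  a <- n11 / n1
  b <- n00 / (n - n1)
  ip <- sqrt(a * b)
  ip[n1 == 0 | n1 == n, ] <- NA_real_
  ip
}

#' Full indicator power analysis of bacterial indicators for fungal targets
#'
#' Rare features (dataset-total reads below `minObservations`) are removed
#' from both tables; indicators are the `topN` most abundant bacterial
#' features, targets the annotated target features with total reads of at
#' least `targetMinReads`. Both sides are binarized (count > 0) for IP;
#' Pearson correlations are computed on the (typically rarefied) counts.
#'
#' @param bactTable bacterial [FeatureTable-class].
#' @param fungiTable fungal [FeatureTable-class]; sample ids must overlap
#'   with `bactTable` (analysis runs on the shared samples).
#' @param taxonomy optional taxonomy data.frame (`feature_id` + rank
#'   columns) used for the target filter (`targetGenus` matched against
#'   the `genus` column) and the per-class IP summary (`class` column).
#' @param topN number of most-abundant bacterial indicators (default 100).
#' @param targetMinReads minimum total reads for a target (default 10).
#' @param minObservations rare-feature cutoff applied to both tables
#'   (default 10).
#' @param targetGenus genus selecting the targets; ignored when `taxonomy`
#'   is NULL (all fungal features then qualify).
#' @return list of class `gutweb_indicator_result`: `ip` (indicators x
#'   targets), `mean_ip_per_indicator`, `mean_ip_per_class` (data.frame with
#'   indicator counts), `tip_per_target`, `correlation`, `row_order`,
#'   `col_order`, `n_undefined`.
#' @export
indicatorAnalysis <- function(bactTable, fungiTable, taxonomy = NULL,
                              topN = 100, targetMinReads = 10,
                              minObservations = 10,
                              targetGenus = "Basidiobolus") {
  stopifnot(methods::is(bactTable, "FeatureTable"),
            methods::is(fungiTable, "FeatureTable"))
  shared <- intersect(sampleNames(bactTable), sampleNames(fungiTable))
  if (length(shared) < 2) stopf("tables share fewer than 2 samples")
  B <- counts(bactTable)[shared, , drop = FALSE]
  FM <- counts(fungiTable)[shared, , drop = FALSE]
  B <- B[, colSums(B) >= minObservations, drop = FALSE]
  FM <- FM[, colSums(FM) >= minObservations, drop = FALSE]

  ord <- order(-colSums(B), colnames(B), method = "radix")
  ind_ids <- colnames(B)[ord[seq_len(min(topN, ncol(B)))]]

  tgt_ids <- colnames(FM)
  if (!is.null(taxonomy) && "genus" %in% names(taxonomy)) {
    hit <- taxonomy$feature_id[!is.na(taxonomy$genus) &
                               taxonomy$genus == targetGenus]
    tgt_ids <- intersect(tgt_ids, hit)
  }
  tgt_ids <- tgt_ids[colSums(FM[, tgt_ids, drop = FALSE]) >= targetMinReads]
  if (!length(tgt_ids)) stopf("no target features left after filtering")

  ip <- .ip_matrix(B[, ind_ids, drop = FALSE], FM[, tgt_ids, drop = FALSE])
  mean_ind <- rowMeans(ip, na.rm = TRUE)
  tip <- colMeans(ip, na.rm = TRUE)

  class_df <- NULL
  if (!is.null(taxonomy) && "class" %in% names(taxonomy)) {
    cls <- taxonomy$class[match(ind_ids, taxonomy$feature_id)]
    cls[is.na(cls)] <- "unclassified"
    agg <- stats::aggregate(mean_ind, by = list(class = cls),
                            FUN = function(v) mean(v, na.rm = TRUE))
    cnt <- as.data.frame(table(class = cls), stringsAsFactors = FALSE)
    class_df <- data.frame(class = agg$class, mean_ip = agg$x,
                           n_indicators = cnt$Freq[match(agg$class, cnt$class)],
                           stringsAsFactors = FALSE)
  }

  hm <- heatmapOrder(B[, ind_ids, drop = FALSE], FM[, tgt_ids, drop = FALSE])

  structure(list(ip = ip,
                 mean_ip_per_indicator = mean_ind,
                 mean_ip_per_class = class_df,
                 tip_per_target = tip,
                 correlation = hm$correlation,
                 row_order = hm$row_order, col_order = hm$col_order,
                 n_undefined = sum(is.na(ip))),
            class = "gutweb_indicator_result")
}

#' @export
print.gutweb_indicator_result <- function(x, ...) {
  cat(sprintf("Indicator power analysis: %d indicators x %d targets (%d undefined IP values)\n",
              nrow(x$ip), ncol(x$ip), x$n_undefined))
  cat(sprintf("  strongest indicator: %s (mean IP %.3f)\n",
              names(which.max(x$mean_ip_per_indicator)),
              max(x$mean_ip_per_indicator, na.rm = TRUE)))
  invisible(x)
}

#' Pearson correlation heatmap ordering by complete-linkage clustering
#'
#' Pearson correlations of abundance vectors across samples for every
#' indicator-target pair; rows (indicators) and columns (targets) are
#' ordered by complete-linkage hierarchical clustering of Euclidean
#' distances between their correlation profiles. Zero-variance vectors
#' give missing correlations; clustering then uses the available values
#' (NA replaced by 0 in the profile distance) with a warning.
#'
#' @param indMat,tgtMat numeric matrices (samples x features).
#' @return list: `correlation` (indicators x targets), `row_order`,
#'   `col_order` (permutations).
#' @export
heatmapOrder <- function(indMat, tgtMat) {
  if (ncol(indMat) < 2 || ncol(tgtMat) < 2)
    stopf("need at least 2 indicators and 2 targets")
  suppressWarnings(cc <- stats::cor(indMat, tgtMat, method = "pearson"))
  prof <- cc
  if (anyNA(prof)) {
    warnf("zero-variance vectors give missing correlations; clustering on available values")
    prof[is.na(prof)] <- 0
  }
  hr <- stats::hclust(stats::dist(prof), method = "complete")
  hc <- stats::hclust(stats::dist(t(prof)), method = "complete")
  list(correlation = cc, row_order = hr$order, col_order = hc$order)
}
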