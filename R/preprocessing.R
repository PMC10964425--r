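# Rarefaction and the filtering rules applied ahead of network inference,
# in declared order: decontaminate -> rarefy -> prevalence filter
# (-> abundance filter for the keystone role analysis).

#' Build a filter report
#'
#' Every filtering operation returns one of these alongside its table so a
#' pipeline run can account for every dropped feature and sample.
#'
#' @param rule rule name.
#' @param featuresBefore,featuresAfter,samplesBefore,samplesAfter counts.
#' @param parameters named list of rule parameters.
#' @param dropped ids dropped by the rule.
#' @return an object of class `gutweb_filter_report`.
#' @export
filterReport <- function(rule, featuresBefore, featuresAfter,
                         samplesBefore, samplesAfter,
                         parameters = list(), dropped = character(0)) {
  stopifnot(featuresAfter <= featuresBefore, samplesAfter <= samplesBefore)
  structure(list(rule = rule,
                 featuresBefore = featuresBefore, featuresAfter = featuresAfter,
                 samplesBefore = samplesBefore, samplesAfter = samplesAfter,
                 parameters = parameters, dropped = dropped),
            class = "gutweb_filter_report")
}

#' @export
print.gutweb_filter_report <- function(x, ...) {
  cat(sprintf("[%s] features %d -> %d; samples %d -> %d\n", x$rule,
              x$featuresBefore, x$featuresAfter, x$samplesBefore, x$samplesAfter))
  invisible(x)
}

#' Rarefy each sample to a fixed depth
#'
#' Subsamples every retained sample without replacement to exactly `depth`
#' total counts (vegan's `rrarefy`); samples whose total is below `depth`
#' are dropped and reported. A zero cell can never become positive.
#'
#' @param table a [FeatureTable-class].
#' @param depth target depth (default 10,000 reads).
#' @param seed integer seed; rarefaction is deterministic under it.
#' @return list with `table` and `report`.
#' @export
rarefyTable <- function(table, depth = 10000, seed = NULL) {
  stopifnot(methods::is(table, "FeatureTable"))
  if (depth < 1) stopf("depth must be >= 1")
  cnt <- counts(table)
  tot <- rowSums(cnt)
  keep <- tot >= depth
  if (!any(keep)) stopf("all samples are below the rarefaction depth %d", depth)
  .set_seed_if(seed)
  sub <- cnt[keep, , drop = FALSE]
  rar <- sub
  exact <- rowSums(sub) == depth
  if (any(!exact)) {
    # the FeatureTable validity already guarantees integer counts, so
    # vegan's heuristic "observed counts" warning is muffled
    rar[!exact, ] <- withCallingHandlers(
      vegan::rrarefy(sub[!exact, , drop = FALSE], depth),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  out <- featureTable(rar, unname(featureMarker(table)), unname(featureDomain(table)))
  rep <- filterReport("rarefy", ncol(cnt), ncol(cnt), nrow(cnt), nrow(rar),
                      parameters = list(depth = depth, seed = seed),
                      dropped = rownames(cnt)[!keep])
  list(table = out, report = rep)
}

#' Keep features present in more than a given fraction of samples
#'
#' Presence is a nonzero count; the comparison is strict (`> minPrevalence`)
#' by default, so at threshold 0.20 a feature present in exactly 20% of
#' samples is dropped.
#'
#' @param table a [FeatureTable-class].
#' @param minPrevalence fraction in (0, 1).
#' @param strict strict (`>`) or inclusive (`>=`) boundary.
#' @return list with `table` and `report`.
#' @export
prevalenceFilter <- function(table, minPrevalence = 0.20, strict = TRUE) {
  stopifnot(methods::is(table, "FeatureTable"))
  if (minPrevalence <= 0 || minPrevalence >= 1)
    stopf("minPrevalence must lie in (0, 1)")
  cnt <- counts(table)
  prev <- colMeans(cnt > 0)
  keep <- if (strict) prev > minPrevalence else prev >= minPrevalence
  if (!any(keep))
    stopf("prevalence filter at %.2f keeps no features; lower the threshold",
          minPrevalence)
  out <- table[, which(keep)]
  rep <- filterReport("prevalence_filter", ncol(cnt), sum(keep),
                      nrow(cnt), nrow(cnt),
                      parameters = list(minPrevalence = minPrevalence,
                                        strict = strict),
                      dropped = colnames(cnt)[!keep])
  list(table = out, report = rep)
}

#' Keep features above dataset-total read and relative-abundance thresholds
#'
#' A feature is kept when its dataset-total reads are at least `minReads`
#' AND its overall relative abundance (feature total over grand total) is
#' at least `minRelAbundance`. Both thresholds are dataset-total, not
#' per-sample.
#'
#' @param table a [FeatureTable-class].
#' @param minReads minimum dataset-total reads (default 10).
#' @param minRelAbundance minimum overall relative abundance (default 0.005).
#' @return list with `table` and `report`.
#' @export
abundanceFilter <- function(table, minReads = 10, minRelAbundance = 0.005) {
  stopifnot(methods::is(table, "FeatureTable"))
  if (minReads < 0 || minRelAbundance < 0) stopf("thresholds must be >= 0")
  cnt <- counts(table)
  tot <- colSums(cnt)
  rel <- tot / sum(tot)
  keep <- tot >= minReads & rel >= minRelAbundance
  out <- table[, which(keep)]
  rep <- filterReport("abundance_filter", ncol(cnt), sum(keep),
                      nrow(cnt), nrow(cnt),
                      parameters = list(minReads = minReads,
                                        minRelAbundance = minRelAbundance),
                      dropped = colnames(cnt)[!keep])
  list(table = out, report = rep)
}

#' Top-n features by total abundance
#'
#' Features are ranked by dataset-total reads, descending; ties are broken
#' by feature id in lexicographic (C-locale) order so the result is
#' reproducible across platforms.
#'
#' @param table a [FeatureTable-class].
#' @param n how many features to keep.
#' @param restrictDomain optional domain label; ranking is then restricted
#'   to features of that domain.
#' @param restrictIds optional explicit feature subset to rank within.
#' @return a [FeatureTable-class] with at most `n` features (all features,
#'   with a warning, when fewer are available).
#' @export
topNByAbundance <- function(table, n, restrictDomain = NULL, restrictIds = NULL) {
  stopifnot(methods::is(table, "FeatureTable"))
  if (n < 1) stopf("n must be >= 1")
  ids <- featureNames(table)
  if (!is.null(restrictDomain))
    ids <- ids[featureDomain(table)[ids] == restrictDomain]
  if (!is.null(restrictIds)) ids <- intersect(ids, restrictIds)
  if (!length(ids)) stopf("no features left after restriction")
  tot <- colSums(counts(table))[ids]
  ord <- order(-tot, ids, method = "radix")
  if (length(ids) < n) {
    warnf("only %d features available; returning all", length(ids))
    n <- length(ids)
  }
  table[, ids[ord[seq_len(n)]]]
}
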