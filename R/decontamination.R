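# Reagent-contaminant screening.
#
# Reagent contaminants enter libraries at a roughly fixed mass, so their
# relative abundance varies inversely with sample DNA concentration. Each
# feature is scored by comparing, in log-frequency vs log-concentration
# space, a contaminant model (slope fixed at -1) against a non-contaminant
# model (slope fixed at 0); the probability threshold below which features
# are discarded is then chosen by sweeping a grid and asking at which value
# the marginal removal still takes more sequences from no-template-control
# (NTC) libraries than from real sample libraries.

#' Score features for the contaminant frequency signature
#'
#' For each feature, over the non-NTC samples where it occurs, least-squares
#' fits of `log(frequency)` with slope fixed at -1 against `log(DNA
#' concentration)` (contaminant model) and slope fixed at 0 (non-contaminant
#' model) are compared through an F-type tail probability on their residual
#' sums of squares. Small scores are contaminant-like. Features occurring in
#' fewer than `minOccurrences` samples get `NA` and are never flagged.
#'
#' @param table a [FeatureTable-class] (counts including any NTC rows).
#' @param metadata matching sample metadata with `dna_concentration` and
#'   `is_ntc`.
#' @param minOccurrences minimum non-NTC occurrences needed to score a
#'   feature; two one-parameter fits on fewer points are degenerate.
#' @return named numeric vector of scores in \[0, 1\] (NA = unscored).
#' @export
frequencyScore <- function(table, metadata, minOccurrences = 5) {
  stopifnot(methods::is(table, "FeatureTable"))
  validateSampleMetadata(metadata)
  if (!all(metadata$sample_id == sampleNames(table)))
    stopf("metadata sample ids must match the table")
  cnt <- counts(table)[!metadata$is_ntc, , drop = FALSE]
  conc <- metadata$dna_concentration[!metadata$is_ntc]
  lib <- rowSums(cnt)
  if (any(lib == 0)) stopf("empty non-NTC libraries cannot be scored")
  scores <- rep(NA_real_, ncol(cnt))
  names(scores) <- colnames(cnt)
  const_conc <- length(unique(conc)) == 1L
  if (const_conc)
    warnf("all DNA concentrations are equal; frequency scores are undefined")
  lx <- log(conc)
  for (j in seq_len(ncol(cnt))) {
    occ <- cnt[, j] > 0
    n <- sum(occ)
    if (n < minOccurrences || const_conc) next
    y <- log(cnt[occ, j] / lib[occ])
    x <- lx[occ]
    rss1 <- sum((y + x - mean(y + x))^2)  # slope -1
    rss0 <- sum((y - mean(y))^2)          # slope  0
    scores[j] <- if (rss1 == 0 && rss0 == 0) 0.5
                 else if (rss1 == 0) 0
                 else stats::pf(rss0 / rss1, n - 1, n - 1, lower.tail = FALSE)
  }
  scores
}

.THRESHOLD_GRID <- seq(0.05, 0.95, by = 0.10)

#' Sweep the probability-threshold grid against NTC and sample libraries
#'
#' At each grid threshold t, features with score < t are flagged; the
#' percentage of total NTC and total sample sequences carried by the
#' flagged features gives the two removal curves used by
#' [selectThreshold()].
#'
#' @param scores named scores from [frequencyScore()].
#' @param table the [FeatureTable-class] the scores were computed on.
#' @param metadata matching sample metadata; at least one NTC sample is
#'   required (the selection rule is NTC-defined).
#' @param grid threshold grid (default 0.05 to 0.95 by 0.10).
#' @return a [ContaminantScreenResult-class] with curves filled in and the
#'   threshold not yet selected.
#' @export
thresholdSweep <- function(scores, table, metadata, grid = .THRESHOLD_GRID) {
  stopifnot(methods::is(table, "FeatureTable"))
  validateSampleMetadata(metadata)
  if (!any(metadata$is_ntc))
    stopf("no NTC samples: the threshold-selection rule is NTC-defined")
  cnt <- counts(table)
  ntc <- metadata$is_ntc
  ntc_feature_tot <- colSums(cnt[ntc, , drop = FALSE])
  smp_feature_tot <- colSums(cnt[!ntc, , drop = FALSE])
  ntc_total <- sum(ntc_feature_tot)
  smp_total <- sum(smp_feature_tot)
  if (ntc_total == 0) stopf("NTC libraries are empty")
  ntc_pct <- smp_pct <- numeric(length(grid))
  for (i in seq_along(grid)) {
    fl <- names(scores)[!is.na(scores) & scores < grid[i]]
    ntc_pct[i] <- 100 * sum(ntc_feature_tot[fl]) / ntc_total
    smp_pct[i] <- 100 * sum(smp_feature_tot[fl]) / smp_total
  }
  methods::new("ContaminantScreenResult",
               score = scores, thresholdGrid = grid,
               ntcRemovedPct = ntc_pct, sampleRemovedPct = smp_pct,
               selectedThreshold = NA_real_, flaggedIds = character(0),
               sweepMode = NA_character_, usedFallback = FALSE)
}

#' Select the decontamination threshold from the sweep curves
#'
#' Scanning the grid in increasing order, the chosen threshold is the last
#' grid value reachable while every marginal step between consecutive grid
#' values still removed strictly more (percentage points) from NTC
#' libraries than from sample libraries, subject to at least `minNtcPct`
#' cumulative removal of total NTC sequences at the chosen value. In
#' `"cumulative"` mode the comparison is instead between the cumulative
#' curves at each threshold. If no grid value qualifies, `fallback` is
#' returned with a warning.
#'
#' @param result a [ContaminantScreenResult-class] from [thresholdSweep()].
#' @param sweepMode `"marginal"` (default) or `"cumulative"`.
#' @param minNtcPct minimum cumulative NTC removal (percent) required.
#' @param fallback threshold used when no grid value qualifies.
#' @return the input result with `selectedThreshold`, `flaggedIds`,
#'   `sweepMode` and `usedFallback` filled in.
#' @export
selectThreshold <- function(result, sweepMode = c("marginal", "cumulative"),
                            minNtcPct = 10, fallback = 0.1) {
  stopifnot(methods::is(result, "ContaminantScreenResult"))
  sweepMode <- match.arg(sweepMode)
  grid <- result@thresholdGrid
  ntc <- result@ntcRemovedPct
  smp <- result@sampleRemovedPct
  k <- length(grid)
  if (sweepMode == "marginal") {
    adv <- diff(ntc) > diff(smp)             # step i: t_i -> t_{i+1}
    eligible <- vapply(seq_len(k), function(i) {
      ntc[i] >= minNtcPct && (i == 1L || all(adv[seq_len(i - 1L)]))
    }, logical(1))
  } else {
    eligible <- ntc >= minNtcPct & ntc > smp
  }
  if (any(eligible)) {
    sel <- grid[max(which(eligible))]
    used_fallback <- FALSE
  } else {
    warnf("no grid threshold qualified (NTC removal < %g%% or no NTC advantage); falling back to %.2f",
          minNtcPct, fallback)
    sel <- fallback
    used_fallback <- TRUE
  }
  result@selectedThreshold <- sel
  result@flaggedIds <- names(result@score)[!is.na(result@score) &
                                           result@score < sel]
  result@sweepMode <- sweepMode
  result@usedFallback <- used_fallback
  methods::validObject(result)
  result
}

#' Screen a table for contaminants end to end
#'
#' [frequencyScore()] + [thresholdSweep()] + [selectThreshold()].
#'
#' @inheritParams frequencyScore
#' @inheritParams selectThreshold
#' @param grid threshold grid.
#' @return a completed [ContaminantScreenResult-class].
#' @export
screenContaminants <- function(table, metadata, sweepMode = "marginal",
                               minOccurrences = 5, grid = .THRESHOLD_GRID,
                               minNtcPct = 10, fallback = 0.1) {
  scores <- frequencyScore(table, metadata, minOccurrences = minOccurrences)
  res <- thresholdSweep(scores, table, metadata, grid = grid)
  selectThreshold(res, sweepMode = sweepMode, minNtcPct = minNtcPct,
                  fallback = fallback)
}

#' Drop flagged contaminants (and optionally NTC rows) from a table
#'
#' @param table a [FeatureTable-class].
#' @param result a completed [ContaminantScreenResult-class].
#' @param metadata optional metadata; when given, NTC rows are dropped from
#'   both table and metadata.
#' @return list with `table` (cleaned), `metadata` (or NULL) and `report`
#'   (a filter report, see [filterReport()]).
#' @export
removeContaminants <- function(table, result, metadata = NULL) {
  stopifnot(methods::is(table, "FeatureTable"),
            methods::is(result, "ContaminantScreenResult"))
  if (is.na(result@selectedThreshold))
    stopf("selectThreshold() has not been applied")
  keep <- setdiff(featureNames(table), result@flaggedIds)
  out <- table[, keep]
  meta <- metadata
  if (!is.null(metadata)) {
    keep_s <- !metadata$is_ntc
    out <- out[metadata$sample_id[keep_s], ]
    meta <- metadata[keep_s, , drop = FALSE]
  }
  rep <- filterReport("decontaminate",
                      featuresBefore = ncol(table), featuresAfter = ncol(out),
                      samplesBefore = nrow(table), samplesAfter = nrow(out),
                      parameters = list(threshold = result@selectedThreshold,
                                        sweepMode = result@sweepMode),
                      dropped = result@flaggedIds)
  list(table = out, metadata = meta, report = rep)
}
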