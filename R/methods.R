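# accessor and show methods

#' @rdname gutweb-accessors
#' @export
setMethod("counts", "FeatureTable", function(object, ...) object@counts)

#' @rdname gutweb-accessors
#' @export
setMethod("sampleNames", "FeatureTable", function(object, ...) rownames(object@counts))

#' @rdname gutweb-accessors
#' @export
setMethod("featureNames", "FeatureTable", function(object, ...) colnames(object@counts))

#' @rdname gutweb-accessors
#' @export
setMethod("featureMarker", "FeatureTable", function(object, ...) {
  stats::setNames(object@featureMarker, colnames(object@counts))
})

#' @rdname gutweb-accessors
#' @export
setMethod("featureDomain", "FeatureTable", function(object, ...) {
  stats::setNames(object@featureDomain, colnames(object@counts))
})

#' @export
setMethod("dim", "FeatureTable", function(x) dim(x@counts))

#' Subset a FeatureTable by samples (i) and/or features (j)
#' @param x a FeatureTable.
#' @param i,j sample / feature index (integer, logical or character).
#' @param ... ignored.
#' @param drop ignored; the result is always a FeatureTable.
#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@counts))
  if (missing(j)) j <- seq_len(ncol(x@counts))
  cnt <- x@counts[i, j, drop = FALSE]
  jj <- stats::setNames(seq_len(ncol(x@counts)), colnames(x@counts))[j]
  featureTable(cnt, x@featureMarker[jj], x@featureDomain[jj])
})

setMethod("show", "FeatureTable", function(object) {
  cnt <- object@counts
  cat(sprintf("FeatureTable: %d samples x %d features\n", nrow(cnt), ncol(cnt)))
  tab <- table(object@featureMarker)
  cat("  markers:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  tab <- table(object@featureDomain)
  cat("  domains:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  total reads: %.0f; sparsity: %.1f%% zero cells\n",
              sum(cnt), 100 * mean(cnt == 0)))
})

#' @rdname gutweb-accessors
#' @export
setMethod("edges", "AssociationNetwork", function(object, ...) object@edgeTable)

#' @rdname gutweb-accessors
#' @export
setMethod("networkNodes", "AssociationNetwork", function(object, ...) {
  stats::setNames(object@nodeDomain, object@nodes)
})

#' @rdname gutweb-accessors
#' @export
setMethod("selectedLambda", "AssociationNetwork", function(object, ...) object@selectedLambda)

#' @rdname gutweb-accessors
#' @export
setMethod("lambdaPath", "AssociationNetwork", function(object, ...) object@lambdaPath)

#' @rdname gutweb-accessors
#' @export
setMethod("instabilityPath", "AssociationNetwork", function(object, ...) {
  stats::setNames(object@instabilityPerLambda,
                  if (length(object@lambdaPath)) signif(object@lambdaPath, 6))
})

setMethod("show", "AssociationNetwork", function(object) {
  m <- nrow(object@edgeTable)
  cat(sprintf("AssociationNetwork: %d nodes, %d edges", length(object@nodes), m))
  if (m) cat(sprintf(" (%.1f%% negative)", 100 * mean(object@edgeTable$sign == "negative")))
  cat("\n")
  if (!is.na(object@selectedLambda)) {
    i <- which.min(abs(object@lambdaPath - object@selectedLambda))
    inst <- if (length(object@instabilityPerLambda)) object@instabilityPerLambda[i] else NA
    cat(sprintf("  selected lambda: %.4g (instability %.4f, %d subsamples)\n",
                object@selectedLambda, inst, object@subsampleCount))
  }
})

#' @rdname gutweb-accessors
#' @export
setMethod("contaminantScores", "ContaminantScreenResult", function(object, ...) object@score)

#' @rdname gutweb-accessors
#' @export
setMethod("flaggedIds", "ContaminantScreenResult", function(object, ...) object@flaggedIds)

#' @rdname gutweb-accessors
#' @export
setMethod("selectedThreshold", "ContaminantScreenResult", function(object, ...) object@selectedThreshold)

#' @rdname gutweb-accessors
#' @export
setMethod("thresholdGrid", "ContaminantScreenResult", function(object, ...) object@thresholdGrid)

#' Sweep curves of a contaminant screen as a data.frame
#' @param object a ContaminantScreenResult.
#' @return data.frame with threshold, ntc_removed_pct, sample_removed_pct.
#' @export
sweepTable <- function(object) {
  stopifnot(methods::is(object, "ContaminantScreenResult"))
  data.frame(threshold = object@thresholdGrid,
             ntc_removed_pct = object@ntcRemovedPct,
             sample_removed_pct = object@sampleRemovedPct)
}

setMethod("show", "ContaminantScreenResult", function(object) {
  cat(sprintf("ContaminantScreenResult: %d features scored (%d unscored)\n",
              sum(!is.na(object@score)), sum(is.na(object@score))))
  if (!is.na(object@selectedThreshold)) {
    cat(sprintf("  selected threshold: %.2f (%s sweep%s); %d features flagged\n",
                object@selectedThreshold, object@sweepMode,
                if (isTRUE(object@usedFallback)) ", fallback" else "",
                length(object@flaggedIds)))
  } else {
    cat("  threshold not yet selected\n")
  }
})
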