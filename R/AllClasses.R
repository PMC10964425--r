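#' FeatureTable: a validated multi-kingdom amplicon count table
#'
#' Integer counts with samples as rows and features (ASVs/OTUs) as columns.
#' Each feature carries a marker tag (`16S` or `ITS`) and a domain tag
#' (`Bacteria`, `Archaea`, `Fungi`, or `unknown`). Feature and sample
#' identifiers are opaque strings; no taxonomy is ever parsed out of them.
#'
#' @slot counts non-negative integral matrix, samples x features, with
#'   unique dimnames.
#' @slot featureMarker character, one of `"16S"`/`"ITS"` per feature.
#' @slot featureDomain character, one of `"Bacteria"`, `"Archaea"`,
#'   `"Fungi"`, `"unknown"` per feature.
#'
#' @seealso [featureTable()] for the user constructor,
#'   [readFeatureTable()]/[writeFeatureTable()] for TSV I/O.
#' @export
setClass("FeatureTable",
  representation(
    counts = "matrix",
    featureMarker = "character",
    featureDomain = "character"
  )
)

.MARKERS <- c("16S", "ITS")
.DOMAINS <- c("Bacteria", "Archaea", "Fungi", "unknown")

setValidity("FeatureTable", function(object) {
  cnt <- object@counts
  msgs <- character(0)
  if (is.null(rownames(cnt)) || is.null(colnames(cnt)))
    msgs <- c(msgs, "counts must have sample (row) and feature (column) names")
  else {
    if (anyDuplicated(rownames(cnt)))
      msgs <- c(msgs, "duplicated sample ids")
    if (anyDuplicated(colnames(cnt)))
      msgs <- c(msgs, "duplicated feature ids")
  }
  if (!all(is_wholenumber(cnt)) || any(cnt < 0))
    msgs <- c(msgs, "counts must be non-negative integers")
  if (length(object@featureMarker) != ncol(cnt))
    msgs <- c(msgs, "featureMarker length must equal the number of features")
  if (length(object@featureDomain) != ncol(cnt))
    msgs <- c(msgs, "featureDomain length must equal the number of features")
  if (!all(object@featureMarker %in% .MARKERS))
    msgs <- c(msgs, sprintf("featureMarker values must be in {%s}",
                            paste(.MARKERS, collapse = ", ")))
  if (!all(object@featureDomain %in% .DOMAINS))
    msgs <- c(msgs, sprintf("featureDomain values must be in {%s}",
                            paste(.DOMAINS, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a FeatureTable
#'
#' @param counts matrix of non-negative integer counts, samples x features.
#'   Row and column names are required and must be unique.
#' @param featureMarker character vector (`"16S"` or `"ITS"`), recycled if
#'   length 1.
#' @param featureDomain character vector (`"Bacteria"`, `"Archaea"`,
#'   `"Fungi"`, `"unknown"`), recycled if length 1.
#' @return a validated [FeatureTable-class] object.
#' @examples
#' m <- matrix(0:5, nrow = 2, dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
#' featureTable(m, "16S", "Bacteria")
#' @export
featureTable <- function(counts, featureMarker = "16S", featureDomain = "unknown") {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (length(featureMarker) == 1L) featureMarker <- rep(featureMarker, ncol(counts))
  if (length(featureDomain) == 1L) featureDomain <- rep(featureDomain, ncol(counts))
  methods::new("FeatureTable", counts = counts,
               featureMarker = unname(featureMarker),
               featureDomain = unname(featureDomain))
}

#' AssociationNetwork: a signed co-occurrence network with inference provenance
#'
#' Undirected signed weighted graph over features, together with the lasso
#' regularization path, per-lambda edge instability and selection metadata
#' from StARS stability selection.
#'
#' @slot nodes character feature ids.
#' @slot nodeDomain character domain label per node.
#' @slot edgeTable data.frame with columns `from`, `to`, `weight`, `sign`.
#' @slot lambdaPath decreasing positive reals (empty for imported networks).
#' @slot selectedLambda numeric(1) or NA.
#' @slot instabilityPerLambda numeric in \[0, 0.5\], parallel to lambdaPath.
#' @slot subsampleCount integer.
#' @slot seed integer.
#' @slot signConflicts integer; count of neighbor-regression sign conflicts.
#' @export
setClass("AssociationNetwork",
  representation(
    nodes = "character",
    nodeDomain = "character",
    edgeTable = "data.frame",
    lambdaPath = "numeric",
    selectedLambda = "numeric",
    instabilityPerLambda = "numeric",
    subsampleCount = "integer",
    seed = "integer",
    signConflicts = "integer"
  )
)

setValidity("AssociationNetwork", function(object) {
  msgs <- character(0)
  ed <- object@edgeTable
  need <- c("from", "to", "weight", "sign")
  if (!all(need %in% names(ed)))
    return(sprintf("edgeTable needs columns {%s}", paste(need, collapse = ", ")))
  if (anyDuplicated(object@nodes)) msgs <- c(msgs, "duplicated node ids")
  if (length(object@nodeDomain) != length(object@nodes))
    msgs <- c(msgs, "nodeDomain length must equal node count")
  if (nrow(ed)) {
    if (!all(ed$from %in% object@nodes) || !all(ed$to %in% object@nodes))
      msgs <- c(msgs, "edge endpoints must be nodes")
    if (any(ed$from == ed$to)) msgs <- c(msgs, "self-edges are not allowed")
    if (any(ed$weight == 0)) msgs <- c(msgs, "zero-weight edges are not allowed")
    ok_sign <- ifelse(ed$weight > 0, "positive", "negative")
    if (!all(ed$sign == ok_sign)) msgs <- c(msgs, "edge sign must match sign(weight)")
  }
  inst <- object@instabilityPerLambda
  if (length(inst) && (any(inst < -1e-12) || any(inst > 0.5 + 1e-12)))
    msgs <- c(msgs, "instability values must lie in [0, 0.5]")
  if (length(object@lambdaPath) > 1 && any(diff(object@lambdaPath) >= 0))
    msgs <- c(msgs, "lambdaPath must be strictly decreasing")
  if (length(msgs)) msgs else TRUE
})

#' Construct an AssociationNetwork from an edge table
#'
#' @param edgeTable data.frame with columns `from`, `to`, `weight` (signed;
#'   a `sign` column is derived).
#' @param nodes node ids; defaults to the ids appearing in edges.
#' @param nodeDomain optional domain label per node.
#' @return an [AssociationNetwork-class] without inference provenance.
#' @examples
#' associationNetwork(data.frame(from = "a", to = "b", weight = 0.3),
#'                    nodes = c("a", "b", "c"))
#' @export
associationNetwork <- function(edgeTable, nodes = NULL, nodeDomain = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edgeTable$from, edgeTable$to)))
  if (nrow(edgeTable)) {
    edgeTable$sign <- ifelse(edgeTable$weight > 0, "positive", "negative")
  } else {
    edgeTable <- data.frame(from = character(0), to = character(0),
                            weight = numeric(0), sign = character(0))
  }
  .new_network(nodes = as.character(nodes), nodeDomain = nodeDomain,
               edgeTable = edgeTable)
}

#' @noRd
.new_network <- function(nodes, nodeDomain = NULL, edgeTable,
                         lambdaPath = numeric(0), selectedLambda = NA_real_,
                         instabilityPerLambda = numeric(0),
                         subsampleCount = 0L, seed = NA_integer_,
                         signConflicts = 0L) {
  if (is.null(nodeDomain)) nodeDomain <- rep("unknown", length(nodes))
  methods::new("AssociationNetwork",
               nodes = nodes, nodeDomain = unname(nodeDomain),
               edgeTable = edgeTable, lambdaPath = lambdaPath,
               selectedLambda = selectedLambda,
               instabilityPerLambda = instabilityPerLambda,
               subsampleCount = as.integer(subsampleCount),
               seed = as.integer(seed),
               signConflicts = as.integer(signConflicts))
}

#' ContaminantScreenResult: scores, sweep curves and the selected threshold
#'
#' Per-feature contaminant-likelihood scores (low = contaminant-like), the
#' removed-percentage curves over the probability-threshold grid for NTC and
#' sample libraries, and the threshold picked by the NTC-based selection rule.
#'
#' @slot score named numeric in \[0, 1\]; NA where the feature occurred in too
#'   few samples to be scored.
#' @slot thresholdGrid the probability thresholds swept (0.05 to 0.95 by 0.10).
#' @slot ntcRemovedPct,sampleRemovedPct percentage of total NTC (resp. sample)
#'   sequences carried by features flagged at each grid threshold.
#' @slot selectedThreshold numeric(1); NA until [selectThreshold()] is applied.
#' @slot flaggedIds features with score < selectedThreshold.
#' @slot sweepMode `"marginal"` or `"cumulative"`.
#' @slot usedFallback logical; TRUE when no grid value qualified.
#' @export
setClass("ContaminantScreenResult",
  representation(
    score = "numeric",
    thresholdGrid = "numeric",
    ntcRemovedPct = "numeric",
    sampleRemovedPct = "numeric",
    selectedThreshold = "numeric",
    flaggedIds = "character",
    sweepMode = "character",
    usedFallback = "logical"
  )
)

setValidity("ContaminantScreenResult", function(object) {
  msgs <- character(0)
  sc <- object@score
  if (is.null(names(sc))) msgs <- c(msgs, "score must be named by feature id")
  if (any(sc < -1e-12 | sc > 1 + 1e-12, na.rm = TRUE))
    msgs <- c(msgs, "scores must lie in [0, 1]")
  k <- length(object@thresholdGrid)
  if (length(object@ntcRemovedPct) != k || length(object@sampleRemovedPct) != k)
    msgs <- c(msgs, "sweep curves must be parallel to the threshold grid")
  if (k > 1 && (is.unsorted(object@ntcRemovedPct) ||
                is.unsorted(object@sampleRemovedPct)))
    msgs <- c(msgs, "removed-percentage curves must be non-decreasing")
  if (length(msgs)) msgs else TRUE
})
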