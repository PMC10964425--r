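# TSV / newick readers and writers with strict validation.
# All files are UTF-8, tab-separated, "." decimal separator.

#' Read a feature count table from TSV
#'
#' The first column holds identifiers. With `orient = "samples_rows"`
#' (the default) rows are samples and columns features; `"features_rows"`
#' accepts the transpose. Cells must be non-negative integers; duplicated
#' sample or feature ids are rejected. Nothing is ever silently dropped.
#'
#' @param path TSV file.
#' @param orient `"samples_rows"` or `"features_rows"`.
#' @param markerMap optional per-feature marker/domain labels: either a
#'   data.frame with columns `feature_id`, `marker`, `domain`, or the path of
#'   a TSV with those columns (as written by [writeFeatureTable()]). Features
#'   absent from the map get marker `"16S"` and domain `"unknown"`.
#' @return a [FeatureTable-class].
#' @export
readFeatureTable <- function(path, orient = c("samples_rows", "features_rows"),
                             markerMap = NULL) {
  orient <- match.arg(orient)
  df <- .read_tsv(path)
  if (ncol(df) < 2L) stopf("feature table '%s' needs an id column plus data", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stopf("duplicated ids in first column of '%s': %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  hdr <- names(df)[-1L]
  if (anyDuplicated(hdr))
    stopf("duplicated column ids in '%s': %s", path,
          paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  bad <- which(!is_wholenumber(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("non-integer or negative count in '%s' at row '%s', column '%s'",
          path, ids[bad[1, 1]], hdr[bad[1, 2]])
  }
  rownames(m) <- ids
  if (orient == "features_rows") m <- t(m)

  marker <- rep("16S", ncol(m))
  domain <- rep("unknown", ncol(m))
  if (!is.null(markerMap)) {
    if (is.character(markerMap) && length(markerMap) == 1L)
      markerMap <- .read_tsv(markerMap)
    need <- c("feature_id", "marker", "domain")
    if (!all(need %in% names(markerMap)))
      stopf("markerMap needs columns {%s}", paste(need, collapse = ", "))
    idx <- match(colnames(m), markerMap$feature_id)
    hit <- !is.na(idx)
    marker[hit] <- markerMap$marker[idx[hit]]
    domain[hit] <- markerMap$domain[idx[hit]]
  }
  featureTable(m, marker, domain)
}

#' Write a FeatureTable (and its feature tags) to TSV
#'
#' Counts go to `path` samples-as-rows with the sample id in the first
#' column; marker/domain tags go to `markerPath` (default: `path` with a
#' `.features.tsv` suffix) so [readFeatureTable()] round-trips losslessly.
#'
#' @param table a [FeatureTable-class].
#' @param path output TSV for counts.
#' @param markerPath output TSV for feature tags, or NULL to skip.
#' @return invisibly, `path`.
#' @export
writeFeatureTable <- function(table, path,
                              markerPath = paste0(path, ".features.tsv")) {
  stopifnot(methods::is(table, "FeatureTable"))
  cnt <- counts(table)
  df <- data.frame(sample_id = rownames(cnt), cnt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
  if (!is.null(markerPath)) {
    .write_tsv(data.frame(feature_id = colnames(cnt),
                          marker = unname(featureMarker(table)),
                          domain = unname(featureDomain(table)),
                          stringsAsFactors = FALSE), markerPath)
  }
  invisible(path)
}

#' Read a taxonomy table from TSV
#'
#' First column `feature_id` (unique), remaining columns ordered lineage
#' ranks (kingdom ... genus/species); missing ranks may be empty or NA.
#'
#' @param path TSV file.
#' @return data.frame with `feature_id` plus rank columns.
#' @export
readTaxonomyTable <- function(path) {
  df <- .read_tsv(path)
  if (names(df)[1L] != "feature_id")
    stopf("taxonomy table '%s' must start with a 'feature_id' column", path)
  if (anyDuplicated(df$feature_id))
    stopf("duplicated feature_id in taxonomy table '%s'", path)
  df
}

#' @rdname readTaxonomyTable
#' @param taxonomy data.frame as returned by `readTaxonomyTable`.
#' @export
writeTaxonomyTable <- function(taxonomy, path) {
  stopifnot("feature_id" %in% names(taxonomy))
  .write_tsv(taxonomy, path)
  invisible(path)
}

.HOST_GROUPS <- c("frog", "lizard", "salamander", "control")

#' Validate a sample metadata data.frame
#'
#' Required columns: `sample_id`, `host_group` (frog/lizard/salamander/
#' control), `host_genus`, `state`, `ecoregion3`, `dna_concentration`
#' (ng/uL, > 0 for non-NTC samples; may be NA for NTCs), `is_ntc` (logical).
#' NTC samples must have `host_group == "control"`.
#'
#' @param metadata data.frame.
#' @return the validated data.frame, invisibly unchanged.
#' @export
validateSampleMetadata <- function(metadata) {
  need <- c("sample_id", "host_group", "host_genus", "state", "ecoregion3",
            "dna_concentration", "is_ntc")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stopf("sample metadata lacks columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id)) stopf("duplicated sample_id in metadata")
  if (!all(metadata$host_group %in% .HOST_GROUPS))
    stopf("host_group values must be in {%s}", paste(.HOST_GROUPS, collapse = ", "))
  if (!is.logical(metadata$is_ntc)) stopf("is_ntc must be logical")
  non_ntc <- !metadata$is_ntc
  conc <- metadata$dna_concentration
  if (any(is.na(conc[non_ntc])) || any(conc[non_ntc] <= 0))
    stopf("dna_concentration must be > 0 for all non-NTC samples")
  if (any(metadata$is_ntc & metadata$host_group != "control"))
    stopf("NTC samples must have host_group = control")
  invisible(metadata)
}

#' Read / write sample metadata TSV
#' @param path TSV file.
#' @return data.frame validated by [validateSampleMetadata()].
#' @export
readSampleMetadata <- function(path) {
  df <- .read_tsv(path)
  if ("is_ntc" %in% names(df)) df$is_ntc <- as.logical(df$is_ntc)
  validateSampleMetadata(df)
  df
}

#' @rdname readSampleMetadata
#' @param metadata validated sample metadata data.frame.
#' @export
writeSampleMetadata <- function(metadata, path) {
  validateSampleMetadata(metadata)
  .write_tsv(metadata, path)
  invisible(path)
}

#' Read a phylogenetic tree from newick
#'
#' Branch lengths are required on every edge (patristic distances are
#' undefined without them) and must be non-negative; tip labels must be
#' unique.
#'
#' @param path newick file.
#' @return an [ape][ape::read.tree] `phylo` object.
#' @export
readTree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stopf("could not parse newick in '%s'", path)
  validateTree(tree, where = path)
  tree
}

#' @rdname readTree
#' @param tree a `phylo` object.
#' @param where label used in error messages.
#' @export
validateTree <- function(tree, where = "tree") {
  if (!inherits(tree, "phylo")) stopf("'%s' is not a phylo object", where)
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge) ||
      any(is.na(tree$edge.length)))
    stopf("'%s' has missing branch lengths; patristic distances would be undefined",
          where)
  if (any(tree$edge.length < 0)) stopf("'%s' has negative branch lengths", where)
  if (anyDuplicated(tree$tip.label)) stopf("'%s' has duplicated tip labels", where)
  invisible(tree)
}

#' @rdname readTree
#' @export
writeTree <- function(tree, path) {
  validateTree(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a network as a Cytoscape-importable edge list
#'
#' Tab-separated columns `source`, `target`, `weight` (signed real), `sign`
#' (`positive`/`negative`), one header line. Isolated nodes are carried in a
#' companion node attribute file when `nodePath` is given.
#'
#' @param net an [AssociationNetwork-class].
#' @param path output TSV.
#' @param nodePath optional TSV of node ids and domain labels.
#' @return invisibly, `path`.
#' @export
writeNetwork <- function(net, path, nodePath = NULL) {
  stopifnot(methods::is(net, "AssociationNetwork"))
  ed <- edges(net)
  .write_tsv(data.frame(source = ed$from, target = ed$to,
                        weight = ed$weight, sign = ed$sign,
                        stringsAsFactors = FALSE), path)
  if (!is.null(nodePath)) {
    nd <- networkNodes(net)
    .write_tsv(data.frame(node = names(nd), domain = unname(nd),
                          stringsAsFactors = FALSE), nodePath)
  }
  invisible(path)
}

#' Read a network edge list written by [writeNetwork()]
#'
#' @param path edge-list TSV.
#' @param nodes optional full node id vector (to restore isolated nodes);
#'   defaults to the ids appearing in edges.
#' @param nodeDomain optional named domain vector over `nodes`.
#' @return an [AssociationNetwork-class] (without inference provenance).
#' @export
readNetwork <- function(path, nodes = NULL, nodeDomain = NULL) {
  df <- .read_tsv(path)
  need <- c("source", "target", "weight", "sign")
  if (!all(need %in% names(df)))
    stopf("edge list '%s' needs columns {%s}", path, paste(need, collapse = ", "))
  if (is.null(nodes)) nodes <- sort(unique(c(df$source, df$target)))
  if (!is.null(nodeDomain)) nodeDomain <- unname(nodeDomain[nodes])
  .new_network(nodes = as.character(nodes), nodeDomain = nodeDomain,
               edgeTable = data.frame(from = as.character(df$source),
                                      to = as.character(df$target),
                                      weight = as.numeric(df$weight),
                                      sign = as.character(df$sign),
                                      stringsAsFactors = FALSE))
}
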