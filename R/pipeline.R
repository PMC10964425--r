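# End-to-end orchestration from a single YAML (or list) config, with
# per-stage seeds derived from one run seed, structured logging and a run
# manifest of input/output digests.

.STAGES <- c("simulate", "decontam", "preprocess", "network", "topology",
             "indicator", "ecology")

#' Validate a pipeline config
#'
#' A config is a list (or YAML file) with `seed` (integer), `out`
#' (directory), `stages` (subset of simulate, decontam, preprocess,
#' network, topology, indicator, ecology, in execution order) and optional
#' per-stage parameter blocks. When `simulate` is absent, `table` (and for
#' decontam/ecology `metadata`) paths must be given. Violations raise a
#' condition of class `gutweb_config_error` before any computation.
#'
#' @param config list or YAML path.
#' @return the validated config list, invisibly.
#' @export
validateConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  bad <- function(fmt, ...) stopf(fmt, ..., class = "gutweb_config_error")
  if (!is.list(config)) bad("config must be a list or YAML file")
  for (key in c("seed", "out", "stages"))
    if (is.null(config[[key]])) bad("config lacks required key '%s'", key)
  if (!is.numeric(config$seed)) bad("'seed' must be an integer")
  stages <- unlist(config$stages)
  unknown <- setdiff(stages, .STAGES)
  if (length(unknown)) bad("unknown stage(s): %s", paste(unknown, collapse = ", "))
  if (!length(stages)) bad("'stages' must name at least one stage")
  needs_table <- setdiff(stages, c("simulate", "ecology"))
  if (!("simulate" %in% stages) && length(c(needs_table, intersect(stages, "ecology")))) {
    if (is.null(config$table)) bad("config lacks required key 'table' (no simulate stage)")
    if (any(c("decontam", "ecology") %in% stages) && is.null(config$metadata))
      bad("config lacks required key 'metadata' (no simulate stage)")
  }
  invisible(config)
}

#' @noRd
.log_stage <- function(manifest, stage, fmt, ...) {
  msg <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
  message(msg)
  manifest$log <- c(manifest$log, msg)
  manifest
}

#' Run the configured pipeline stages end to end
#'
#' Stages execute in declared order; any stage failure aborts with the
#' stage name after writing the partial manifest. No stage mutates its
#' inputs on disk; outputs are written under `config$out` and every file
#' is digested (md5) into the manifest, so identical config + inputs
#' reproduce identical digests for deterministic stages.
#'
#' @param config list or YAML path, see [validateConfig()].
#' @return the run manifest (list): `configHash`, `seeds`, `stages`,
#'   `fileDigests`, `filterReports`, `log`.
#' @export
runAll <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  validateConfig(config)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  manifest <- list(configHash = unname(tools::md5sum(cfg_file)),
                   seeds = list(), stages = character(0),
                   fileDigests = character(0), filterReports = list(),
                   log = character(0))
  unlink(cfg_file)
  stages <- unlist(config$stages)
  seed <- config$seed
  state <- new.env(parent = emptyenv())

  if (!is.null(config$table)) {
    state$table <- readFeatureTable(config$table,
                                    markerMap = config$markerMap)
    manifest$fileDigests[config$table] <- unname(tools::md5sum(config$table))
  }
  if (!is.null(config$metadata)) {
    state$metadata <- readSampleMetadata(config$metadata)
    manifest$fileDigests[config$metadata] <- unname(tools::md5sum(config$metadata))
  }

  emit <- function(obj, name) {
    path <- file.path(out, name)
    if (methods::is(obj, "FeatureTable")) writeFeatureTable(obj, path)
    else if (methods::is(obj, "AssociationNetwork")) writeNetwork(obj, path)
    else .write_tsv(obj, path)
    for (f in c(path, if (methods::is(obj, "FeatureTable"))
                        paste0(path, ".features.tsv")))
      manifest$fileDigests[f] <<- unname(tools::md5sum(f))
    path
  }

  for (stage in stages) {
    manifest$seeds[[stage]] <- deriveSeed(seed, stage)
    res <- tryCatch(
      switch(stage,
        simulate = {
          pre <- if (is.null(config$simulate$preset)) "contam"
                 else config$simulate$preset
          sim <- simulatePreset(pre, seed = seed, outDir = file.path(out, "simulated"))
          state$table <- sim$table
          state$metadata <- sim$metadata
          manifest <- .log_stage(manifest, stage, "preset '%s' generated (%d samples x %d features)",
                                 pre, nrow(sim$table), ncol(sim$table))
          manifest
        },
        decontam = {
          scr <- screenContaminants(state$table, state$metadata,
                                    sweepMode = if (is.null(config$decontam$sweepMode))
                                      "marginal" else config$decontam$sweepMode)
          emit(sweepTable(scr), "decontam_sweep.tsv")
          emit(data.frame(feature_id = names(contaminantScores(scr)),
                          score = unname(contaminantScores(scr)),
                          flagged = names(contaminantScores(scr)) %in% flaggedIds(scr)),
               "decontam_scores.tsv")
          cln <- removeContaminants(state$table, scr, state$metadata)
          state$table <- cln$table
          state$metadata <- cln$metadata
          manifest$filterReports$decontam <- cln$report
          emit(state$table, "counts_decontaminated.tsv")
          manifest <- .log_stage(manifest, stage,
                                 "threshold %.2f; %d features flagged",
                                 selectedThreshold(scr), length(flaggedIds(scr)))
          manifest
        },
        preprocess = {
          pp <- config$preprocess
          depth <- if (is.null(pp$depth)) 10000 else pp$depth
          prev <- if (is.null(pp$prevalence)) 0.20 else pp$prevalence
          rr <- rarefyTable(state$table, depth = depth,
                            seed = manifest$seeds[[stage]])
          manifest$filterReports$rarefy <- rr$report
          pf <- prevalenceFilter(rr$table, minPrevalence = prev)
          manifest$filterReports$prevalence <- pf$report
          state$table <- pf$table
          if (!is.null(state$metadata))
            state$metadata <- state$metadata[
              state$metadata$sample_id %in% sampleNames(state$table), ,
              drop = FALSE]
          emit(state$table, "counts_preprocessed.tsv")
          manifest <- .log_stage(manifest, stage,
                                 "rarefied to %d, prevalence > %.2f: %d samples x %d features kept",
                                 depth, prev, nrow(state$table), ncol(state$table))
          manifest
        },
        network = {
          np <- config$network
          net <- inferNetwork(state$table,
                              betaTarget = if (is.null(np$beta)) 0.05 else np$beta,
                              nSubsamples = if (is.null(np$subsamples)) 20 else np$subsamples,
                              nLambda = if (is.null(np$nlambda)) 30 else np$nlambda,
                              seed = manifest$seeds[[stage]])
          state$network <- net
          emit(net, "network_edges.tsv")
          emit(data.frame(lambda = lambdaPath(net),
                          instability = net@instabilityPerLambda),
               "network_instability.tsv")
          manifest <- .log_stage(manifest, stage, "%d edges at lambda %.4g",
                                 nrow(edges(net)), selectedLambda(net))
          manifest
        },
        topology = {
          if (is.null(state$network)) stopf("topology stage needs a network")
          prof <- nodeTopology(state$network)
          gs <- globalStats(state$network)
          emit(prof, "node_topology.tsv")
          emit(data.frame(statistic = names(gs),
                          value = unlist(gs)), "global_stats.tsv")
          hub <- hubSubnetwork(state$network,
                               topFraction = if (is.null(config$topology$topFraction))
                                 0.30 else config$topology$topFraction)
          emit(hub, "hub_subnetwork.tsv")
          manifest <- .log_stage(manifest, stage,
                                 "%d modules, modularity %.3f, %d hub nodes",
                                 gs$n_modules, gs$modularity,
                                 length(hub@nodes))
          manifest
        },
        indicator = {
          dom <- featureDomain(state$table)
          bact <- state$table[, which(dom == "Bacteria")]
          fung <- state$table[, which(dom == "Fungi")]
          ia <- indicatorAnalysis(bact, fung,
                                  topN = if (is.null(config$indicator$topN)) 100
                                         else config$indicator$topN,
                                  minObservations = if (is.null(config$indicator$minObservations)) 10
                                         else config$indicator$minObservations)
          emit(data.frame(indicator = rownames(ia$ip), ia$ip,
                          check.names = FALSE), "indicator_ip.tsv")
          emit(data.frame(target = names(ia$tip_per_target),
                          tip = unname(ia$tip_per_target)), "indicator_tip.tsv")
          manifest <- .log_stage(manifest, stage, "%d x %d IP matrix",
                                 nrow(ia$ip), ncol(ia$ip))
          manifest
        },
        ecology = {
          d <- brayCurtis(state$table)
          meta <- state$metadata[match(sampleNames(state$table),
                                       state$metadata$sample_id), , drop = FALSE]
          pm <- permanova(d, ~ host_group, data = meta,
                          nPerm = if (is.null(config$ecology$nperm)) 999
                                  else config$ecology$nperm,
                          seed = manifest$seeds[[stage]])
          emit(pm$aov_table, "permanova.tsv")
          manifest <- .log_stage(manifest, stage, "PERMANOVA host F = %.3f, p = %.4g",
                                 pm$aov_table$F[1], pm$aov_table$p[1])
          manifest
        },
        stopf("unknown stage '%s'", stage)
      ),
      error = function(e) {
        manifest$failedStage <- stage
        saveRDS_path <- file.path(out, "manifest_partial.yaml")
        yaml::write_yaml(.manifest_yaml(manifest), saveRDS_path)
        stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
      })
    manifest <- res
    manifest$stages <- c(manifest$stages, stage)
  }
  yaml::write_yaml(.manifest_yaml(manifest), file.path(out, "manifest.yaml"))
  manifest
}

#' @noRd
.manifest_yaml <- function(manifest) {
  list(configHash = manifest$configHash,
       seeds = manifest$seeds,
       stages = manifest$stages,
       fileDigests = as.list(manifest$fileDigests),
       log = manifest$log)
}
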