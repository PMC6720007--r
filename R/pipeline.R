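#' @include AllClasses.R
NULL

#' Assemble and validate a pipeline configuration
#'
#' Collects the input paths, output directory and every threshold of the
#' end-to-end run into one record. Module selection for candidate
#' nomination is a user decision: give either `moduleId` (an explicit
#' module) or `moduleGeneset` (the name of a gene set; the module whose
#' gene content is most enriched for that set is selected, mirroring
#' selection of a module by its biological-process profile). With neither,
#' the module with the overall strongest enrichment that contains at least
#' one miRNA is selected.
#'
#' @param matrixPath,samplesPath expression matrix TSV and sample sheet.
#' @param sourcePaths character vector of per-source target-table TSVs.
#' @param universePath gene universe file (one symbol per line).
#' @param ppiPath PPI edge-list TSV.
#' @param gmtPath gene-set collection (GMT).
#' @param biomarkerPath per-subject biomarker CSV.
#' @param outDir output directory.
#' @param qMax,fcMin,exprMin DE reporting cutoffs.
#' @param minSampleFrac,negctrlQuantile detection-filter parameters.
#' @param minSources consensus threshold.
#' @param resolution module-detection resolution.
#' @param topK candidates retained by traffic score.
#' @param maxJaccard redundancy threshold for top enriched terms.
#' @param moduleId,moduleGeneset module selection (see above).
#' @param covariate biomarker covariate column name.
#' @param seed integer seed for module detection.
#' @return A `PipelineConfig` (named list, class `"PipelineConfig"`).
#' @seealso [runPipeline()], [validateInputs()]
#' @export
pipelineConfig <- function(matrixPath, samplesPath, sourcePaths,
                           universePath, ppiPath, gmtPath, biomarkerPath,
                           outDir,
                           qMax = 0.05, fcMin = 0.5, exprMin = 5,
                           minSampleFrac = 0.5, negctrlQuantile = 0.9,
                           minSources = 2L, resolution = 1, topK = 10L,
                           maxJaccard = 0.5, moduleId = NULL,
                           moduleGeneset = NULL, covariate = "diameter_mm",
                           seed = 1L) {
  cfg <- list(matrixPath = matrixPath, samplesPath = samplesPath,
              sourcePaths = sourcePaths, universePath = universePath,
              ppiPath = ppiPath, gmtPath = gmtPath,
              biomarkerPath = biomarkerPath, outDir = outDir,
              qMax = qMax, fcMin = fcMin, exprMin = exprMin,
              minSampleFrac = minSampleFrac,
              negctrlQuantile = negctrlQuantile,
              minSources = as.integer(minSources), resolution = resolution,
              topK = as.integer(topK), maxJaccard = maxJaccard,
              moduleId = moduleId, moduleGeneset = moduleGeneset,
              covariate = covariate, seed = as.integer(seed))
  for (f in c("qMax", "minSampleFrac", "negctrlQuantile", "maxJaccard"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("configuration error: '", f, "' must be in [0, 1]", call. = FALSE)
  if (cfg$minSources < 1L)
    stop("configuration error: 'minSources' must be >= 1", call. = FALSE)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Pipeline configuration pointing at a simulated study bundle
#'
#' @param dir directory written by [writeStudyBundle()].
#' @param outDir output directory (default `<dir>/results`).
#' @param ... further arguments passed to [pipelineConfig()].
#' @return A `PipelineConfig`.
#' @export
pipelineConfigFromDir <- function(dir, outDir = file.path(dir, "results"),
                                  ...) {
  sources <- sort(list.files(dir, pattern = "^targets_.*\\.tsv$",
                             full.names = TRUE))
  pipelineConfig(
    matrixPath = file.path(dir, "expression.tsv"),
    samplesPath = file.path(dir, "samples.tsv"),
    sourcePaths = sources,
    universePath = file.path(dir, "universe.txt"),
    ppiPath = file.path(dir, "ppi.tsv"),
    gmtPath = file.path(dir, "genesets.gmt"),
    biomarkerPath = file.path(dir, "biomarker.csv"),
    outDir = outDir, ...)
}

#' Validate pipeline input files
#'
#' Schema checks for every input file plus id cross-reference checks
#' (target-table miRNAs vs the expression matrix, PPI endpoints vs the
#' gene universe). Problems that prevent a run are collected as errors;
#' everything else as warnings.
#'
#' @param config a `PipelineConfig`.
#' @return A list with character vectors `errors` and `warnings`.
#' @export
validateInputs <- function(config) {
  errors <- character(); warnings <- character()
  note <- function(cond) conditionMessage(cond)
  tryRead <- function(what, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        errors <<- c(errors, paste0(what, ": ", note(e)))
        NULL
      }),
      warning = function(w) {
        warnings <<- c(warnings, paste0(what, ": ", note(w)))
        invokeRestart("muffleWarning")
      })
  }
  for (p in c(config$matrixPath, config$samplesPath, config$sourcePaths,
              config$universePath, config$ppiPath, config$gmtPath,
              config$biomarkerPath))
    if (!file.exists(p)) errors <- c(errors, paste0("missing file: ", p))
  if (length(errors))
    return(list(errors = errors, warnings = warnings))

  expt <- tryRead("expression matrix",
                  readExpressionMatrix(config$matrixPath,
                                       config$samplesPath))
  tables <- lapply(config$sourcePaths, function(p)
    tryRead(paste0("target table ", basename(p)), readTargetTable(p)))
  universe <- tryRead("gene universe", readGeneUniverse(config$universePath))
  ppi <- tryRead("PPI edge list", readPpiTable(config$ppiPath))
  tryRead("gene sets", readGmt(config$gmtPath))
  tryRead("biomarker table", readBiomarkerTable(config$biomarkerPath))

  if (!is.null(expt)) {
    probes <- normalizeMirnaIds(rownames(expt))
    for (i in seq_along(tables)) {
      tab <- tables[[i]]
      if (is.null(tab)) next
      hit <- normalizeMirnaIds(tab$mirna) %in% probes
      if (!any(hit))
        warnings <- c(warnings, paste0(
          "target table ", basename(config$sourcePaths[i]),
          ": no miRNA id matches the expression matrix"))
    }
  }
  if (!is.null(ppi) && !is.null(universe)) {
    out <- setdiff(unique(c(ppi$gene_a, ppi$gene_b)), universe)
    if (length(out))
      warnings <- c(warnings, paste0(length(out),
        " PPI gene(s) absent from the universe: ",
        paste(utils::head(out, 5L), collapse = ", "),
        if (length(out) > 5L) ", ..." else ""))
  }
  list(errors = errors, warnings = warnings)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full prioritization and biomarker pipeline
#'
#' Executes detection filtering, differential expression, consensus target
#' integration, network construction, traffic scoring, module detection,
#' per-module enrichment, candidate ranking within the selected module,
#' and biomarker evaluation, writing every intermediate table to
#' `config$outDir`. Any stage failure aborts with the stage name and
#' cause; outputs of earlier stages are retained.
#'
#' @param config a `PipelineConfig`.
#' @return The run manifest (invisible a list, also written as
#'   `manifest.json`): per-stage counts, the nominated candidate, the
#'   biomarker summary, output paths and their MD5 checksums, and the
#'   configuration echo.
#' @examples
#' dir <- tempfile()
#' writeStudyBundle(simulateStudy(simulationConfig(
#'   nMirnas = 120, nGenes = 80, nCommunities = 4, seed = 5)), dir)
#' mf <- runPipeline(pipelineConfigFromDir(dir))
#' mf$nominatedCandidate
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outDir, f)
  paths <- character()

  expt <- .stage("read_inputs",
                 readExpressionMatrix(config$matrixPath, config$samplesPath))
  tables <- .stage("read_inputs", lapply(config$sourcePaths, readTargetTable))
  names(tables) <- sub("\\.tsv$", "", basename(config$sourcePaths))
  universe <- .stage("read_inputs", readGeneUniverse(config$universePath))
  ppi <- .stage("read_inputs", readPpiTable(config$ppiPath))
  geneSets <- .stage("read_inputs", readGmt(config$gmtPath))
  serum <- .stage("read_inputs", readBiomarkerTable(config$biomarkerPath))

  filtered <- .stage("detection_filter",
                     detectionFilter(expt, config$minSampleFrac,
                                     config$negctrlQuantile))
  de <- .stage("differential_expression",
               differentialExpression(filtered, qMax = config$qMax,
                                      fcMin = config$fcMin,
                                      exprMin = config$exprMin))
  paths["de"] <- writeDETable(de, out("de_table.tsv"))

  deMirnas <- de$mirna_id[de$passes_cutoffs]
  ces <- .stage("consensus",
                consensusEdges(tables, universe = universe,
                               mirnas = deMirnas,
                               minSources = config$minSources))
  utils::write.table(edgeTable(ces), out("consensus_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths["consensus"] <- out("consensus_edges.tsv")

  net <- .stage("network", buildNetwork(ces, ppi, universe = universe))
  traffic <- .stage("network", trafficScores(net))
  partition <- .stage("modules",
                      detectModules(net, resolution = config$resolution,
                                    seed = config$seed))
  g <- networkGraph(net)
  edf <- igraph::as_data_frame(g, what = "edges")
  utils::write.table(
    data.frame(node_a = edf$from, node_b = edf$to, edge_kind = edf$kind),
    out("network_edges.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  paths["network_edges"] <- out("network_edges.tsv")
  mem <- moduleMembership(partition)
  nodeTab <- data.frame(node_id = igraph::V(g)$name,
                        node_kind = igraph::V(g)$kind,
                        module_id = unname(mem[igraph::V(g)$name]),
                        traffic = traffic$traffic[
                          match(igraph::V(g)$name, traffic$node)])
  utils::write.table(nodeTab, out("network_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths["network_nodes"] <- out("network_nodes.tsv")

  moduleIds <- sort(unique(mem))
  enrich <- .stage("enrichment", {
    res <- lapply(moduleIds, function(m) {
      genes <- names(mem)[mem == m]
      genes <- genes[genes %in% universe]
      if (length(genes) == 0L) return(NULL)
      r <- enrichGeneSets(genes, geneSets, universe)
      cbind(module_id = m, r)
    })
    do.call(rbind, res)
  })
  utils::write.table(enrich, out("module_enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths["enrichment"] <- out("module_enrichment.tsv")

  selected <- .stage("module_selection", {
    hasMirna <- vapply(moduleIds, function(m) {
      nodes <- names(mem)[mem == m]
      any(traffic$kind[match(nodes, traffic$node)] == "mirna")
    }, logical(1))
    eligible <- moduleIds[hasMirna]
    if (!is.null(config$moduleId)) {
      as.integer(config$moduleId)
    } else if (!is.null(config$moduleGeneset)) {
      sub <- enrich[enrich$term == config$moduleGeneset &
                      enrich$module_id %in% eligible, , drop = FALSE]
      if (!nrow(sub)) stop("gene set '", config$moduleGeneset,
                           "' not found in any eligible module")
      sub$module_id[which.min(sub$p)]
    } else {
      sub <- enrich[enrich$module_id %in% eligible, , drop = FALSE]
      if (!nrow(sub)) stop("no eligible module with enrichment results")
      sub$module_id[which.min(sub$p)]
    }
  })

  deNorm <- de
  deNorm$mirna_id <- normalizeMirnaIds(deNorm$mirna_id)
  ranking <- .stage("rank",
                    rankCandidates(partition, traffic, deNorm,
                                   moduleId = selected, k = config$topK))
  utils::write.table(ranking, out("candidate_ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths["ranking"] <- out("candidate_ranking.tsv")

  cmp <- .stage("biomarker", compareGroups(serum))
  roc <- .stage("biomarker", rocAnalysis(serum))
  corr <- .stage("biomarker",
                 correlateCovariate(serum, config$covariate))
  utils::write.table(roc@curve, out("roc_points.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths["roc"] <- out("roc_points.tsv")

  manifest <- list(
    counts = list(
      probes = nrow(expt), samples = ncol(expt),
      detected = nrow(filtered), tested = nrow(de),
      de_passing = sum(de$passes_cutoffs),
      de_up = sum(de$passes_cutoffs & de$direction == "up"),
      de_down = sum(de$passes_cutoffs & de$direction == "down"),
      consensus_edges = nrow(edgeTable(ces)),
      ppi_edges = sum(edf$kind == "ppi"),
      network_nodes = igraph::vcount(g),
      network_edges = igraph::ecount(g),
      modules = length(moduleIds),
      module_sizes = as.integer(table(mem)),
      ranked_candidates = nrow(ranking)
    ),
    selectedModule = selected,
    nominatedCandidate = if (nrow(ranking)) ranking$mirna_id[1L] else NA,
    biomarker = list(
      test = cmp$test, p_value = cmp$p_value,
      fold_change = cmp$fold_change,
      auc = auc(roc),
      youden_threshold = roc@youdenThreshold,
      sensitivity = roc@sensitivityAtYouden,
      specificity = roc@specificityAtYouden,
      spearman_rho = corr$rho, spearman_p = corr$p_value
    ),
    outputs = as.list(paths),
    checksums = as.list(tools::md5sum(unname(paths))),
    config = unclass(config)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
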