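#' @include AllGenerics.R
#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.checkFraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    return(sprintf("'%s' must be a single value in [0, 1]", name))
  NULL
}

.checkCount <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    return(sprintf("'%s' must be a single integer >= %d", name, min))
  NULL
}

.checkPositive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    return(sprintf("'%s' must be a single positive value", name))
  NULL
}

#' Simulation configuration for the synthetic study generator
#'
#' Holds every parameter of the synthetic data generators: cohort sizes and
#' effect structure of the tissue expression experiment, the planted-partition
#' gene interaction graph, the multi-source target-prediction tables, and the
#' serum biomarker cohort whose separation is calibrated to a target AUC.
#' Defaults reproduce the study conditions the package is designed around:
#' a 19 + 19 tissue cohort, a 28 + 20 serum cohort, three prediction sources,
#' eight gene communities and a target AUC of 0.87.
#'
#' @slot seed integer; base random seed for all generators.
#' @slot nCases,nControls integer; tissue-cohort group sizes (>= 2 each).
#' @slot nMirnas integer; number of real miRNA probes.
#' @slot nNegctrlProbes integer; number of negative-control probes.
#' @slot fracDE fraction of miRNAs with a planted group difference.
#' @slot deLog2fcMagnitude positive; magnitude of planted log2 fold changes.
#' @slot withinGroupSd positive; within-group SD of log2 signal.
#' @slot baselineMean baseline mean log2 signal of expressed miRNAs.
#' @slot detectionDropoutRate fraction of miRNAs that are unexpressed
#'   (below negative-control-level signal in all samples).
#' @slot nGenes integer; size of the disease gene universe.
#' @slot nCommunities integer; number of planted gene communities.
#' @slot pWithin,pBetween within-/between-community PPI edge probabilities;
#'   `pWithin > pBetween`.
#' @slot nSources integer; number of target-prediction sources.
#' @slot edgesPerMirna integer; true target edges planted per DE miRNA.
#' @slot sourceAgreement probability a true edge is reported by any one source.
#' @slot targetAuc target binormal AUC of the serum biomarker, in (0.5, 1).
#' @slot serumSdLog positive; log-scale SD of serum levels in each group.
#' @slot nSerumCases,nSerumControls integer; serum-cohort group sizes.
#'
#' @seealso [simulationConfig()], [simulateStudy()]
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer",
    nCases = "integer", nControls = "integer",
    nMirnas = "integer", nNegctrlProbes = "integer",
    fracDE = "numeric", deLog2fcMagnitude = "numeric",
    withinGroupSd = "numeric", baselineMean = "numeric",
    detectionDropoutRate = "numeric",
    nGenes = "integer", nCommunities = "integer",
    pWithin = "numeric", pBetween = "numeric",
    nSources = "integer", edgesPerMirna = "integer",
    sourceAgreement = "numeric",
    targetAuc = "numeric", serumSdLog = "numeric",
    nSerumCases = "integer", nSerumControls = "integer"
  ),
  prototype(
    seed = 1L,
    nCases = 19L, nControls = 19L,
    nMirnas = 600L, nNegctrlProbes = 50L,
    fracDE = 0.1, deLog2fcMagnitude = 1.0,
    withinGroupSd = 0.5, baselineMean = 7,
    detectionDropoutRate = 0.2,
    nGenes = 400L, nCommunities = 8L,
    pWithin = 0.2, pBetween = 0.005,
    nSources = 3L, edgesPerMirna = 25L,
    sourceAgreement = 0.8,
    targetAuc = 0.87, serumSdLog = 0.69,
    nSerumCases = 28L, nSerumControls = 20L
  )
)

setValidity("SimulationConfig", function(object) {
  msgs <- c(
    .checkCount(object@seed, "seed"),
    .checkCount(object@nCases, "nCases", min = 2L),
    .checkCount(object@nControls, "nControls", min = 2L),
    .checkCount(object@nMirnas, "nMirnas", min = 1L),
    .checkCount(object@nNegctrlProbes, "nNegctrlProbes", min = 1L),
    .checkFraction(object@fracDE, "fracDE"),
    .checkPositive(object@deLog2fcMagnitude, "deLog2fcMagnitude"),
    .checkPositive(object@withinGroupSd, "withinGroupSd"),
    .checkFraction(object@detectionDropoutRate, "detectionDropoutRate"),
    .checkCount(object@nGenes, "nGenes", min = 1L),
    .checkCount(object@nCommunities, "nCommunities", min = 1L),
    .checkFraction(object@pWithin, "pWithin"),
    .checkFraction(object@pBetween, "pBetween"),
    .checkCount(object@nSources, "nSources", min = 1L),
    .checkCount(object@edgesPerMirna, "edgesPerMirna", min = 1L),
    .checkFraction(object@sourceAgreement, "sourceAgreement"),
    .checkPositive(object@serumSdLog, "serumSdLog"),
    .checkCount(object@nSerumCases, "nSerumCases", min = 2L),
    .checkCount(object@nSerumControls, "nSerumControls", min = 2L)
  )
  if (is.numeric(object@pWithin) && is.numeric(object@pBetween) &&
      length(object@pWithin) == 1L && length(object@pBetween) == 1L &&
      !is.na(object@pWithin) && !is.na(object@pBetween) &&
      object@pWithin <= object@pBetween)
    msgs <- c(msgs, "'pWithin' must exceed 'pBetween'")
  if (!is.numeric(object@targetAuc) || length(object@targetAuc) != 1L ||
      is.na(object@targetAuc) ||
      object@targetAuc <= 0.5 || object@targetAuc >= 1)
    msgs <- c(msgs, "'targetAuc' must be a single value in (0.5, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimulationConfig
#'
#' @param ... named values overriding the defaults documented in
#'   [SimulationConfig-class]. Counts may be given as plain numerics.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nMirnas = 100, fracDE = 0.2)
#' cfg
#' @export
simulationConfig <- function(...) {
  args <- list(...)
  if (length(args) && (is.null(names(args)) || any(names(args) == "")))
    stop("all arguments to simulationConfig() must be named", call. = FALSE)
  slots <- getSlots("SimulationConfig")
  bad <- setdiff(names(args), names(slots))
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (nm in names(args)) {
    if (slots[[nm]] == "integer" && is.numeric(args[[nm]]) &&
        !is.na(args[[nm]]) && args[[nm]] == as.integer(args[[nm]]))
      args[[nm]] <- as.integer(args[[nm]])
  }
  do.call(new, c("SimulationConfig", args))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  tissue cohort : %d cases / %d controls, %d miRNAs (+%d neg ctrl)\n",
              object@nCases, object@nControls, object@nMirnas,
              object@nNegctrlProbes))
  cat(sprintf("  planted DE    : %.0f%% at |log2FC| = %.2g (sd %.2g)\n",
              100 * object@fracDE, object@deLog2fcMagnitude,
              object@withinGroupSd))
  cat(sprintf("  gene universe : %d genes, %d communities (p_in %.3g / p_out %.3g)\n",
              object@nGenes, object@nCommunities, object@pWithin,
              object@pBetween))
  cat(sprintf("  predictions   : %d sources, agreement %.2g, %d edges/miRNA\n",
              object@nSources, object@sourceAgreement, object@edgesPerMirna))
  cat(sprintf("  serum cohort  : %d / %d, target AUC %.2f (sd_log %.2g)\n",
              object@nSerumCases, object@nSerumControls, object@targetAuc,
              object@serumSdLog))
  invisible(NULL)
})

#' Ground truth of a simulated study
#'
#' Records everything the generators planted so downstream recovery can be
#' scored: the DE miRNAs with their signed log2 fold changes, the community
#' of every gene, the true miRNA-target edges, the log-scale serum shift,
#' and the designated candidate miRNA (the strongest planted effect, whose
#' targets concentrate in one community).
#'
#' @slot deMirnas data.frame with columns `mirna`, `log2fc`.
#' @slot communityOfGene named integer; gene id -> community id.
#' @slot trueEdges data.frame with columns `mirna`, `gene`.
#' @slot serumShiftLog numeric; log-scale case-control mean difference.
#' @slot candidateMirna character; id of the planted candidate (or empty).
#' @slot candidateCommunity integer; community its targets concentrate in.
#' @export
setClass("GroundTruth",
  representation(
    deMirnas = "data.frame",
    communityOfGene = "integer",
    trueEdges = "data.frame",
    serumShiftLog = "numeric",
    candidateMirna = "character",
    candidateCommunity = "integer"
  ),
  prototype(
    deMirnas = data.frame(mirna = character(), log2fc = numeric()),
    trueEdges = data.frame(mirna = character(), gene = character()),
    communityOfGene = integer(),
    serumShiftLog = numeric(),
    candidateMirna = character(),
    candidateCommunity = integer()
  )
)

setValidity("GroundTruth", function(object) {
  msgs <- character()
  if (!all(c("mirna", "log2fc") %in% names(object@deMirnas)))
    msgs <- c(msgs, "deMirnas must have columns 'mirna' and 'log2fc'")
  if (!all(c("mirna", "gene") %in% names(object@trueEdges)))
    msgs <- c(msgs, "trueEdges must have columns 'mirna' and 'gene'")
  if (length(object@communityOfGene) &&
      is.null(names(object@communityOfGene)))
    msgs <- c(msgs, "communityOfGene must be named by gene id")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth\n")
  cat(sprintf("  %d planted DE miRNAs, %d true target edges, %d genes in %d communities\n",
              nrow(object@deMirnas), nrow(object@trueEdges),
              length(object@communityOfGene),
              length(unique(object@communityOfGene))))
  if (length(object@candidateMirna))
    cat(sprintf("  candidate: %s (community %d)\n", object@candidateMirna,
                object@candidateCommunity))
  invisible(NULL)
})

#' miRNA expression experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding log2
#' expression signal in assay `"log2signal"`, a `group` column
#' (`"case"`/`"control"`) in `colData`, and an `isNegativeControl` logical
#' column in `rowData` flagging control probes used by the detection filter.
#'
#' @seealso [MirnaExperiment()], [detectionFilter()],
#'   [differentialExpression()]
#' @export
setClass("MirnaExperiment", contains = "SummarizedExperiment")

setValidity("MirnaExperiment", function(object) {
  msgs <- character()
  if (!"log2signal" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'log2signal' is required")
  if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "duplicate row ids are not allowed")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% names(cd)) {
    msgs <- c(msgs, "colData must contain a 'group' column")
  } else {
    grp <- as.character(cd$group)
    if (any(is.na(grp)) || !all(grp %in% c("case", "control")))
      msgs <- c(msgs, "every sample must be labelled 'case' or 'control'")
    else if (sum(grp == "case") < 2L || sum(grp == "control") < 2L)
      msgs <- c(msgs, "at least 2 samples per group are required")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!"isNegativeControl" %in% names(rd) ||
      !is.logical(rd$isNegativeControl) || anyNA(rd$isNegativeControl))
    msgs <- c(msgs,
              "rowData must contain a complete logical 'isNegativeControl'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MirnaExperiment
#'
#' @param log2signal numeric matrix of log2 signal, probes in rows (named),
#'   samples in columns (named).
#' @param group character/factor of `"case"`/`"control"`, one per sample.
#' @param isNegativeControl logical per row; defaults to all `FALSE`.
#' @param rowData optional extra row annotation (data.frame/DataFrame).
#' @return A [MirnaExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(40, 7), 10, 4,
#'             dimnames = list(paste0("mir", 1:10), paste0("s", 1:4)))
#' MirnaExperiment(m, group = c("case", "case", "control", "control"))
#' @export
MirnaExperiment <- function(log2signal, group,
                            isNegativeControl = rep(FALSE, nrow(log2signal)),
                            rowData = NULL) {
  if (!is.matrix(log2signal) || !is.numeric(log2signal))
    stop("'log2signal' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(log2signal)) || is.null(colnames(log2signal)))
    stop("'log2signal' must have row and column names", call. = FALSE)
  rd <- DataFrame(isNegativeControl = as.logical(isNegativeControl))
  if (!is.null(rowData)) rd <- cbind(rd, DataFrame(rowData))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = SimpleList(log2signal = log2signal),
    colData = DataFrame(group = as.character(group),
                        row.names = colnames(log2signal)),
    rowData = rd
  )
  new("MirnaExperiment", se)
}

#' @describeIn MirnaExperiment-class group labels, one per sample
#' @param x a `MirnaExperiment`.
#' @export
setMethod("sampleGroups", "MirnaExperiment", function(x) {
  as.character(SummarizedExperiment::colData(x)$group)
})

#' @describeIn MirnaExperiment-class logical negative-control flag per row
#' @export
setMethod("isNegativeControl", "MirnaExperiment", function(x) {
  SummarizedExperiment::rowData(x)$isNegativeControl
})

setMethod("show", "MirnaExperiment", function(object) {
  grp <- sampleGroups(object)
  cat(sprintf("MirnaExperiment: %d probes (%d negative-control) x %d samples (%d case / %d control)\n",
              nrow(object), sum(isNegativeControl(object)), ncol(object),
              sum(grp == "case"), sum(grp == "control")))
  invisible(NULL)
})

#' Consensus miRNA-target edge set
#'
#' Predicted miRNA-to-gene interactions retained by the multi-source
#' consensus rule: an edge is kept only when reported by at least
#' `minSources` distinct prediction sources, its miRNA belongs to the query
#' set (typically the differentially expressed miRNAs) and its gene to the
#' disease gene universe.
#'
#' @slot edges data.frame with columns `mirna`, `gene`, `support` (integer
#'   number of supporting sources) and `sources` (comma-joined labels).
#' @slot minSources integer consensus threshold.
#' @seealso [consensusEdges()], [targetsOf()]
#' @export
setClass("ConsensusEdgeSet",
  representation(edges = "data.frame", minSources = "integer"),
  prototype(edges = data.frame(mirna = character(), gene = character(),
                               support = integer(), sources = character()),
            minSources = 2L)
)

setValidity("ConsensusEdgeSet", function(object) {
  e <- object@edges
  msgs <- character()
  if (!all(c("mirna", "gene", "support", "sources") %in% names(e)))
    return("edges must have columns mirna, gene, support, sources")
  if (nrow(e)) {
    nsrc <- lengths(strsplit(e$sources, ",", fixed = TRUE))
    if (!all(e$support == nsrc))
      msgs <- c(msgs, "support must equal the number of listed sources")
    if (any(e$support < object@minSources))
      msgs <- c(msgs, "all edges must meet the minSources threshold")
    if (anyDuplicated(paste(e$mirna, e$gene)))
      msgs <- c(msgs, "duplicate miRNA-gene edges are not allowed")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ConsensusEdgeSet-class the edge table
#' @param x a `ConsensusEdgeSet`.
#' @export
setMethod("edgeTable", "ConsensusEdgeSet", function(x) x@edges)

setMethod("show", "ConsensusEdgeSet", function(object) {
  cat(sprintf("ConsensusEdgeSet: %d edges (>= %d sources), %d miRNAs -> %d genes\n",
              nrow(object@edges), object@minSources,
              length(unique(object@edges$mirna)),
              length(unique(object@edges$gene))))
  invisible(NULL)
})

#' Heterogeneous miRNA-gene regulatory network
#'
#' An undirected, unweighted graph whose nodes are miRNAs and genes and whose
#' edges are either consensus miRNA-target predictions (`mirna_gene`) or
#' protein-protein interactions (`ppi`). Edge kinds are kept as attributes
#' for filtering but ignored by the centrality and module computations.
#'
#' @slot graph an `igraph` object with vertex attributes `name`, `kind`
#'   (`"mirna"`/`"gene"`) and edge attribute `kind`
#'   (`"mirna_gene"`/`"ppi"`).
#' @seealso [buildNetwork()], [trafficScores()], [detectModules()]
#' @export
setClass("RegulatoryNetwork", representation(graph = "ANY"))

setValidity("RegulatoryNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  msgs <- character()
  vk <- igraph::V(g)$kind
  ek <- igraph::E(g)$kind
  if (is.null(vk) || !all(vk %in% c("mirna", "gene")))
    msgs <- c(msgs, "every node needs kind 'mirna' or 'gene'")
  if (igraph::ecount(g)) {
    if (is.null(ek) || !all(ek %in% c("mirna_gene", "ppi")))
      msgs <- c(msgs, "every edge needs kind 'mirna_gene' or 'ppi'")
    if (any(igraph::which_loop(g)))
      msgs <- c(msgs, "self-loops are not allowed")
    if (any(igraph::which_multiple(g)))
      msgs <- c(msgs, "parallel edges are not allowed")
    if (!is.null(vk) && !is.null(ek) &&
        all(vk %in% c("mirna", "gene")) &&
        all(ek %in% c("mirna_gene", "ppi"))) {
      ends <- igraph::ends(g, igraph::E(g), names = FALSE)
      k1 <- vk[ends[, 1L]]; k2 <- vk[ends[, 2L]]
      mg <- ek == "mirna_gene"
      if (any(mg & !((k1 == "mirna" & k2 == "gene") |
                     (k1 == "gene" & k2 == "mirna"))))
        msgs <- c(msgs, "mirna_gene edges must join a miRNA and a gene")
      if (any(!mg & !(k1 == "gene" & k2 == "gene")))
        msgs <- c(msgs, "ppi edges must join two genes")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn RegulatoryNetwork-class the underlying igraph
#' @param x a `RegulatoryNetwork`.
#' @export
setMethod("networkGraph", "RegulatoryNetwork", function(x) x@graph)

setMethod("show", "RegulatoryNetwork", function(object) {
  g <- object@graph
  vk <- igraph::V(g)$kind
  ek <- if (igraph::ecount(g)) igraph::E(g)$kind else character()
  cat(sprintf("RegulatoryNetwork: %d nodes (%d miRNA, %d gene), %d edges (%d miRNA-gene, %d PPI)\n",
              igraph::vcount(g), sum(vk == "mirna"), sum(vk == "gene"),
              igraph::ecount(g), sum(ek == "mirna_gene"), sum(ek == "ppi")))
  invisible(NULL)
})

#' Module partition of a network
#'
#' @slot membership named integer; node id -> module id in 1..M.
#' @slot modularity numeric; modularity of the partition.
#' @seealso [detectModules()]
#' @export
setClass("ModulePartition",
  representation(membership = "integer", modularity = "numeric"),
  prototype(membership = integer(), modularity = NA_real_)
)

setValidity("ModulePartition", function(object) {
  m <- object@membership
  msgs <- character()
  if (length(m)) {
    if (is.null(names(m)) || anyNA(m))
      msgs <- c(msgs, "membership must be a complete named integer vector")
    else if (!setequal(unique(m), seq_len(max(m))))
      msgs <- c(msgs, "module ids must be consecutive integers starting at 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ModulePartition-class node -> module assignment
#' @param x a `ModulePartition`.
#' @export
setMethod("moduleMembership", "ModulePartition", function(x) x@membership)

#' @describeIn ModulePartition-class modularity of the partition
#' @export
setMethod("modularityScore", "ModulePartition", function(x) x@modularity)

setMethod("show", "ModulePartition", function(object) {
  sizes <- table(object@membership)
  cat(sprintf("ModulePartition: %d nodes in %d modules (modularity %.3f)\n",
              length(object@membership), length(sizes), object@modularity))
  if (length(sizes))
    cat("  module sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  invisible(NULL)
})

#' ROC analysis result
#'
#' Full ROC curve of a positive-valued biomarker (case = positive class,
#' level above threshold = test-positive), trapezoidal AUC, and the
#' Youden-optimal operating point.
#'
#' @slot curve data.frame with columns `threshold`, `sensitivity`,
#'   `specificity`, one row per swept threshold.
#' @slot auc numeric AUC in `[0, 1]`.
#' @slot youdenThreshold threshold maximizing sensitivity + specificity - 1
#'   (ties broken toward higher specificity).
#' @slot sensitivityAtYouden,specificityAtYouden operating point at the
#'   Youden threshold.
#' @slot nCases,nControls group sizes used.
#' @seealso [rocAnalysis()]
#' @export
setClass("RocResult",
  representation(curve = "data.frame", auc = "numeric",
                 youdenThreshold = "numeric",
                 sensitivityAtYouden = "numeric",
                 specificityAtYouden = "numeric",
                 nCases = "integer", nControls = "integer")
)

setValidity("RocResult", function(object) {
  msgs <- character()
  if (!all(c("threshold", "sensitivity", "specificity") %in%
           names(object@curve)))
    msgs <- c(msgs, "curve needs threshold, sensitivity, specificity columns")
  if (length(object@auc) != 1L || is.na(object@auc) ||
      object@auc < 0 || object@auc > 1)
    msgs <- c(msgs, "auc must be a single value in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn RocResult-class the area under the curve
#' @param x a `RocResult`.
#' @export
setMethod("auc", "RocResult", function(x) x@auc)

#' @describeIn RocResult-class Youden-optimal threshold and operating point
#' @export
setMethod("youdenPoint", "RocResult", function(x) {
  c(threshold = x@youdenThreshold,
    sensitivity = x@sensitivityAtYouden,
    specificity = x@specificityAtYouden)
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: AUC %.3f (%d cases vs %d controls)\n",
              object@auc, object@nCases, object@nControls))
  cat(sprintf("  Youden cutoff %.4g: sensitivity %.1f%%, specificity %.1f%%\n",
              object@youdenThreshold, 100 * object@sensitivityAtYouden,
              100 * object@specificityAtYouden))
  invisible(NULL)
})
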