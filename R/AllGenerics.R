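#' Betweenness ("traffic") scores for network nodes
#'
#' @param x a [RegulatoryNetwork-class] object.
#' @param ... further arguments passed to methods.
#' @return A data.frame with columns `node`, `kind` and `traffic`.
#' @export
setGeneric("trafficScores", function(x, ...) standardGeneric("trafficScores"))

#' Decompose a network into modules by modularity optimization
#'
#' @param x a [RegulatoryNetwork-class] object.
#' @param ... further arguments passed to methods.
#' @return A [ModulePartition-class] object.
#' @export
setGeneric("detectModules", function(x, ...) standardGeneric("detectModules"))

#' Consensus target genes of one miRNA
#'
#' @param x a [ConsensusEdgeSet-class] object.
#' @param mirna single miRNA identifier.
#' @param ... further arguments passed to methods.
#' @return Character vector of gene ids (empty if the miRNA has no edges).
#' @export
setGeneric("targetsOf", function(x, mirna, ...) standardGeneric("targetsOf"))

#' Edge table of a consensus edge set
#'
#' @param x a [ConsensusEdgeSet-class] object.
#' @return A data.frame with columns `mirna`, `gene`, `support`, `sources`.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Underlying igraph object of a network
#'
#' @param x a [RegulatoryNetwork-class] object.
#' @return An `igraph` graph with `kind` vertex and edge attributes.
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' Node-to-module assignment of a partition
#'
#' @param x a [ModulePartition-class] object.
#' @return Named integer vector mapping node id to module id (1..M).
#' @export
setGeneric("moduleMembership", function(x) standardGeneric("moduleMembership"))

#' Modularity value of a partition
#'
#' @param x a [ModulePartition-class] object.
#' @return Single numeric modularity value.
#' @export
setGeneric("modularityScore", function(x) standardGeneric("modularityScore"))

#' Area under the ROC curve
#'
#' @param x a [RocResult-class] object.
#' @return Single numeric AUC in `[0, 1]`.
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' Operating point at the Youden-optimal threshold
#'
#' @param x a [RocResult-class] object.
#' @return Named numeric vector with `threshold`, `sensitivity`, `specificity`.
#' @export
setGeneric("youdenPoint", function(x) standardGeneric("youdenPoint"))

#' Sample group labels of an expression experiment
#'
#' @param x a [MirnaExperiment-class] object.
#' @return Character vector of `"case"` / `"control"` labels, one per sample.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' Negative-control indicator of expression rows
#'
#' @param x a [MirnaExperiment-class] object.
#' @return Logical vector, `TRUE` for negative-control probes.
#' @export
setGeneric("isNegativeControl", function(x) standardGeneric("isNegativeControl"))
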