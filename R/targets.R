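#' @include AllClasses.R
NULL

#' Normalize miRNA identifiers across prediction sources
#'
#' Prediction databases disagree on species prefixes; `"strip_species"`
#' lowercases ids and removes a leading `hsa-`/`mmu-` prefix so that e.g.
#' `hsa-miR-574-5p` and `miR-574-5p` match.
#'
#' @param ids character vector of miRNA ids.
#' @param mode `"strip_species"` (default) or `"none"`.
#' @return Normalized ids.
#' @examples
#' normalizeMirnaIds(c("hsa-miR-574-5p", "MIR-21-5p"))
#' @export
normalizeMirnaIds <- function(ids, mode = c("strip_species", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(ids)
  sub("^(hsa|mmu)-", "", tolower(ids))
}

.edgeKey <- function(m, g) paste(m, g, sep = "\r")

#' Multi-source consensus of predicted miRNA-target edges
#'
#' An edge is retained when it appears in at least `minSources` distinct
#' prediction tables (duplicates within one source counted once), its miRNA
#' belongs to `mirnas` (typically the differentially expressed set) and its
#' gene belongs to the disease gene `universe`.
#'
#' @param tables list of per-source data.frames whose first two columns are
#'   miRNA id and gene id (any further columns, e.g. scores, are ignored).
#' @param universe character vector of admissible gene ids.
#' @param mirnas character vector of admissible miRNA ids.
#' @param minSources consensus threshold (default 2).
#' @param idNormalization passed to [normalizeMirnaIds()]; applied to both
#'   the tables and `mirnas`.
#' @return A [ConsensusEdgeSet-class]; edges sorted by miRNA then gene.
#' @examples
#' tabs <- list(a = data.frame(mirna = "m1", gene = "G1"),
#'              b = data.frame(mirna = "m1", gene = "G1"),
#'              c = data.frame(mirna = "m1", gene = "G2"))
#' consensusEdges(tabs, universe = c("G1", "G2"), mirnas = "m1")
#' @export
consensusEdges <- function(tables, universe, mirnas, minSources = 2L,
                           idNormalization = c("strip_species", "none")) {
  idNormalization <- match.arg(idNormalization)
  if (!is.list(tables) || length(tables) < minSources)
    stop("input error: need at least 'minSources' (", minSources,
         ") source tables", call. = FALSE)
  if (!length(universe))
    stop("input error: empty gene universe", call. = FALSE)
  if (!length(mirnas))
    stop("input error: empty miRNA set", call. = FALSE)
  if (is.null(names(tables)) || any(names(tables) == ""))
    names(tables) <- sprintf("source_%d", seq_along(tables))
  mirnas <- unique(normalizeMirnaIds(mirnas, idNormalization))
  universe <- unique(universe)

  per <- lapply(names(tables), function(s) {
    tab <- tables[[s]]
    if (ncol(tab) < 2L)
      stop("input error: source '", s, "' needs >= 2 columns", call. = FALSE)
    m <- normalizeMirnaIds(as.character(tab[[1L]]), idNormalization)
    g <- as.character(tab[[2L]])
    keep <- !duplicated(.edgeKey(m, g))
    data.frame(mirna = m[keep], gene = g[keep], source = s,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per)
  all <- all[all$mirna %in% mirnas & all$gene %in% universe, , drop = FALSE]
  key <- .edgeKey(all$mirna, all$gene)
  supp <- as.integer(table(key)[key])
  first <- !duplicated(key)
  srcs <- vapply(split(all$source, key), function(s)
    paste(sort(unique(s)), collapse = ","), character(1))
  edges <- data.frame(mirna = all$mirna[first], gene = all$gene[first],
                      support = supp[first],
                      sources = unname(srcs[key[first]]),
                      stringsAsFactors = FALSE)
  edges <- edges[edges$support >= minSources, , drop = FALSE]
  edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  new("ConsensusEdgeSet", edges = edges, minSources = as.integer(minSources))
}

#' @describeIn ConsensusEdgeSet-class genes with a consensus edge from one
#'   miRNA (empty if the miRNA is absent)
#' @param mirna single miRNA id (normalization is the caller's concern).
#' @export
setMethod("targetsOf", "ConsensusEdgeSet", function(x, mirna) {
  stopifnot(length(mirna) == 1L)
  sort(unique(x@edges$gene[x@edges$mirna == mirna]))
})
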