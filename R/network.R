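#' @include AllClasses.R
NULL

.canonicalPairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  list(a = a, b = b)
}

#' Build the heterogeneous miRNA-gene / PPI network
#'
#' Combines consensus miRNA-target edges with a protein-protein interaction
#' edge list into one undirected, unweighted graph. Node kinds
#' (`mirna`/`gene`) and edge kinds (`mirna_gene`/`ppi`) are tagged;
#' duplicate edges collapse to one and self-loops in the PPI input are
#' dropped with a warning.
#'
#' @param consensus a [ConsensusEdgeSet-class].
#' @param ppi data.frame whose first two columns are interacting gene ids.
#' @param universe optional gene universe; when given, PPI edges with an
#'   endpoint outside it are rejected (dropped with a message).
#' @return A [RegulatoryNetwork-class].
#' @examples
#' tabs <- list(a = data.frame(mirna = "m1", gene = "G1"),
#'              b = data.frame(mirna = "m1", gene = "G1"))
#' ces <- consensusEdges(tabs, universe = c("G1", "G2"), mirnas = "m1")
#' buildNetwork(ces, ppi = data.frame(gene_a = "G1", gene_b = "G2"))
#' @export
buildNetwork <- function(consensus, ppi, universe = NULL) {
  stopifnot(is(consensus, "ConsensusEdgeSet"))
  ce <- edgeTable(consensus)
  if (!nrow(ce)) stop("input error: empty consensus edge set", call. = FALSE)
  if (is.null(ppi) || !nrow(ppi))
    stop("input error: empty PPI edge list", call. = FALSE)
  ga <- as.character(ppi[[1L]]); gb <- as.character(ppi[[2L]])
  mirnaIds <- unique(ce$mirna)
  if (any(c(ga, gb) %in% mirnaIds))
    stop("input error: PPI edge list names a miRNA id", call. = FALSE)
  loops <- ga == gb
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped from the PPI input")
    ga <- ga[!loops]; gb <- gb[!loops]
  }
  if (!is.null(universe)) {
    ok <- ga %in% universe & gb %in% universe
    if (any(!ok))
      message(sum(!ok), " PPI edge(s) outside the gene universe rejected")
    ga <- ga[ok]; gb <- gb[ok]
  }
  cp <- .canonicalPairs(ga, gb)
  keep <- !duplicated(.edgeKey(cp$a, cp$b))
  ppiEdges <- data.frame(from = cp$a[keep], to = cp$b[keep],
                         kind = "ppi", stringsAsFactors = FALSE)
  mgEdges <- data.frame(from = ce$mirna, to = ce$gene, kind = "mirna_gene",
                        stringsAsFactors = FALSE)
  edges <- rbind(mgEdges, ppiEdges)
  genes <- sort(unique(c(ce$gene, ppiEdges$from, ppiEdges$to)))
  nodes <- data.frame(
    name = c(sort(mirnaIds), genes),
    kind = rep(c("mirna", "gene"), c(length(mirnaIds), length(genes))),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  new("RegulatoryNetwork", graph = g)
}

#' @describeIn RegulatoryNetwork-class exact betweenness ("traffic")
#'   scores: Brandes accumulation over all shortest paths of the undirected
#'   unweighted graph, endpoints excluded, pair contributions split evenly
#'   across equal-length shortest paths. With `normalized = TRUE` scores
#'   are divided by `(n - 1)(n - 2) / 2`. With a `partition`, scores are
#'   computed within each module's induced subgraph instead of the full
#'   network.
#' @param normalized logical; normalize by the number of node pairs.
#' @param partition optional [ModulePartition-class] for per-module scores.
#' @export
setMethod("trafficScores", "RegulatoryNetwork",
          function(x, normalized = FALSE, partition = NULL) {
  g <- networkGraph(x)
  score <- function(gr) {
    n <- igraph::vcount(gr)
    if (n == 0L) return(numeric())
    if (igraph::ecount(gr) == 0L) return(numeric(n))
    ends <- igraph::ends(gr, igraph::E(gr), names = FALSE)
    brandes_betweenness(n, ends - 1L)
  }
  if (is.null(partition)) {
    traffic <- score(g)
    names(traffic) <- igraph::V(g)$name
  } else {
    mem <- moduleMembership(partition)
    traffic <- numeric(igraph::vcount(g))
    names(traffic) <- igraph::V(g)$name
    for (m in sort(unique(mem))) {
      sub <- igraph::induced_subgraph(g, names(mem)[mem == m])
      traffic[igraph::V(sub)$name] <- score(sub)
    }
  }
  if (normalized) {
    n <- igraph::vcount(g)
    denom <- (n - 1) * (n - 2) / 2
    if (denom > 0) traffic <- traffic / denom
  }
  data.frame(node = igraph::V(g)$name, kind = igraph::V(g)$kind,
             traffic = unname(traffic[igraph::V(g)$name]),
             stringsAsFactors = FALSE, row.names = NULL)
})

#' @describeIn RegulatoryNetwork-class modularity-maximizing module
#'   decomposition by seeded greedy multi-level (Louvain) refinement;
#'   disconnected components are handled independently by the algorithm.
#'   Module ids are renumbered 1..M in order of first appearance along the
#'   vertex order, so a fixed seed gives a reproducible labelling.
#' @param resolution modularity resolution (higher values give more,
#'   smaller modules; default 1).
#' @param seed integer seed controlling the refinement order.
#' @export
setMethod("detectModules", "RegulatoryNetwork",
          function(x, resolution = 1, seed = 1L) {
  g <- networkGraph(x)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  mem <- igraph::membership(cl)
  relab <- as.integer(match(mem, unique(mem)))
  names(relab) <- igraph::V(g)$name
  new("ModulePartition", membership = relab,
      modularity = igraph::modularity(g, relab))
})

#' Rank candidate miRNAs of one module
#'
#' Takes the `k` miRNAs of the module with the highest traffic scores
#' (ties broken by ascending q-value then lexicographic id), then reorders
#' them by ascending q-value; the rank-1 miRNA is the nominated candidate.
#'
#' @param partition a [ModulePartition-class].
#' @param traffic traffic-score table from [trafficScores()].
#' @param de differential-expression table from
#'   [differentialExpression()].
#' @param moduleId module to rank within.
#' @param k number of top-traffic miRNAs retained (default 10).
#' @return data.frame with columns `mirna_id`, `module_id`,
#'   `traffic_score`, `q_value`, `rank`; zero rows (with a warning) when
#'   the module contains no ranked miRNA.
#' @export
rankCandidates <- function(partition, traffic, de, moduleId, k = 10L) {
  stopifnot(is(partition, "ModulePartition"))
  mem <- moduleMembership(partition)
  inMod <- names(mem)[mem == moduleId]
  cand <- traffic[traffic$kind == "mirna" & traffic$node %in% inMod, ,
                  drop = FALSE]
  cand$q_value <- de$q_value[match(cand$node, de$mirna_id)]
  cand <- cand[!is.na(cand$q_value), , drop = FALSE]
  if (!nrow(cand)) {
    warning("module ", moduleId, " contains no miRNA with a DE record")
    return(data.frame(mirna_id = character(), module_id = integer(),
                      traffic_score = numeric(), q_value = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  }
  cand <- cand[order(-cand$traffic, cand$q_value, cand$node), , drop = FALSE]
  cand <- utils::head(cand, k)
  cand <- cand[order(cand$q_value, cand$node), , drop = FALSE]
  data.frame(mirna_id = cand$node,
             module_id = as.integer(moduleId),
             traffic_score = cand$traffic,
             q_value = cand$q_value,
             rank = seq_len(nrow(cand)),
             stringsAsFactors = FALSE, row.names = NULL)
}
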