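# Independent oracles used across the suite. These deliberately avoid the
# code paths they check (Brandes accumulation, hash-count consensus, the
# ROC sweep).

# exhaustive all-shortest-paths betweenness: enumerate every shortest path
# of every unordered pair and count interior appearances, split evenly
referenceBetweenness <- function(g) {
  n <- igraph::vcount(g)
  nms <- igraph::V(g)$name
  if (is.null(nms)) nms <- paste0("n", seq_len(n))
  bc <- numeric(n)
  if (n < 3L) return(stats::setNames(bc, nms))
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      sp <- suppressWarnings(
        igraph::all_shortest_paths(g, from = s, to = t)$res)
      if (!length(sp)) next
      inner <- unlist(lapply(sp, function(p) {
        v <- as.integer(p)
        v[-c(1L, length(v))]
      }))
      if (length(inner)) {
        tb <- table(inner)
        idx <- as.integer(names(tb))
        bc[idx] <- bc[idx] + as.numeric(tb) / length(sp)
      }
    }
  }
  stats::setNames(bc, nms)
}

# wrap an arbitrary simple undirected graph as an all-gene network so the
# traffic-score machinery can run on it
geneNetwork <- function(g) {
  if (is.null(igraph::V(g)$name))
    g <- igraph::set_vertex_attr(g, "name",
                                 value = paste0("n", seq_len(igraph::vcount(g))))
  g <- igraph::set_vertex_attr(g, "kind", value = "gene")
  if (igraph::ecount(g))
    g <- igraph::set_edge_attr(g, "kind", value = "ppi")
  new("RegulatoryNetwork", graph = g)
}

# brute-force multi-source consensus: deduplicate each table, concatenate,
# count keys
bruteConsensus <- function(tables, minSources) {
  keys <- unlist(lapply(tables, function(tab)
    unique(paste(tab[[1L]], tab[[2L]], sep = "|"))))
  tb <- table(keys)
  sort(names(tb)[tb >= minSources])
}

# tie-corrected Mann-Whitney AUC: P(case > control) + 0.5 P(tie)
rankSumAUC <- function(cases, ctrls) {
  mean(outer(cases, ctrls, ">") + 0.5 * outer(cases, ctrls, "=="))
}

randomBiomarkerTable <- function(n1, n2, values) {
  data.frame(
    subject_id = sprintf("s%02d", seq_len(n1 + n2)),
    group = rep(c("case", "control"), c(n1, n2)),
    level = sample(values, n1 + n2, replace = TRUE),
    stringsAsFactors = FALSE)
}
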