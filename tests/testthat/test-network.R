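twoSourceTabs <- function(edges) {
  tab <- data.frame(mirna = edges$mirna, gene = edges$gene)
  list(a = tab, b = tab)
}

test_that("network construction tags kinds and deduplicates edges", {
  ces <- consensusEdges(
    twoSourceTabs(data.frame(mirna = c("m1", "m2"), gene = c("G1", "G2"))),
    universe = c("G1", "G2", "G3", "G4"), mirnas = c("m1", "m2"),
    idNormalization = "none")
  ppi <- data.frame(gene_a = c("G3", "G3", "G4"),
                    gene_b = c("G4", "G4", "G3"))  # duplicates + reversal
  net <- buildNetwork(ces, ppi)
  g <- networkGraph(net)
  # disjoint consensus/ppi gene sets: nodes = miRNAs + both gene sets
  expect_equal(igraph::vcount(g), 2L + 2L + 2L)
  expect_equal(igraph::ecount(g), 3L)
  expect_equal(sum(igraph::E(g)$kind == "ppi"), 1L)

  expect_error(buildNetwork(ces, data.frame(gene_a = "m1", gene_b = "G1")),
               "miRNA")
  expect_warning(
    buildNetwork(ces, data.frame(gene_a = c("G3", "G3"),
                                 gene_b = c("G3", "G4"))),
    "self-loop")
})

test_that("degree sequence equals a recount from the input tables", {
  set.seed(31)
  cfg <- simulationConfig(seed = 31, nMirnas = 120, nGenes = 80,
                          nCommunities = 4)
  sim <- simulateExpression(cfg)
  tabs <- simulateTargetTables(cfg, sim$truth)
  ppi <- simulatePPI(cfg, sim$truth)
  genes <- names(sim$truth@communityOfGene)
  ces <- consensusEdges(tabs, genes, sim$truth@deMirnas$mirna,
                        idNormalization = "none")
  net <- buildNetwork(ces, ppi, universe = genes)
  g <- networkGraph(net)
  e <- edgeTable(ces)
  cp <- paste(pmin(ppi$gene_a, ppi$gene_b), pmax(ppi$gene_a, ppi$gene_b))
  ppiDedup <- ppi[!duplicated(cp), ]
  ends <- c(e$mirna, e$gene, ppiDedup$gene_a, ppiDedup$gene_b)
  expected <- table(ends)
  got <- igraph::degree(g)
  expect_equal(unname(got[names(expected)]), as.integer(expected))
})

test_that("traffic scores reproduce closed forms on star and path graphs", {
  star <- igraph::make_star(5, mode = "undirected")
  ts <- trafficScores(geneNetwork(star))
  expect_equal(ts$traffic[1], 6)            # (n-1)(n-2)/2 at the hub
  expect_equal(ts$traffic[-1], rep(0, 4))   # leaves score 0
  tsn <- trafficScores(geneNetwork(star), normalized = TRUE)
  expect_equal(tsn$traffic[1], 1)

  path <- igraph::make_graph(~ a - b, b - c)
  tp <- trafficScores(geneNetwork(path))
  expect_equal(tp$traffic[match(c("a", "b", "c"), tp$node)], c(0, 1, 0))
})

test_that("traffic scores equal exhaustive path enumeration and igraph", {
  set.seed(32)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.2, 0.7))
    ref <- referenceBetweenness(g)
    ts <- trafficScores(geneNetwork(g))
    expect_equal(ts$traffic, unname(ref)[match(ts$node, names(ref))],
                 tolerance = 1e-10)
    expect_equal(ts$traffic, unname(igraph::betweenness(g)),
                 tolerance = 1e-10)
  }
})

test_that("betweenness conservation holds exactly on trees", {
  # on a tree each pair has one path; total betweenness = sum over pairs of
  # interior path lengths
  set.seed(33)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    g <- igraph::sample_tree(n)
    ts <- trafficScores(geneNetwork(g))
    d <- igraph::distances(g)
    expected <- sum(d[upper.tri(d)] - 1)
    expect_equal(sum(ts$traffic), expected, tolerance = 1e-10)
  }
})

test_that("module detection recovers disjoint cliques and is seed-deterministic", {
  c1 <- igraph::make_full_graph(5)
  c2 <- igraph::make_full_graph(5)
  g <- igraph::disjoint_union(c1, c2)
  net <- geneNetwork(g)
  part <- detectModules(net, seed = 1)
  mem <- moduleMembership(part)
  expect_equal(length(unique(mem)), 2L)
  expect_equal(length(unique(mem[1:5])), 1L)
  expect_equal(length(unique(mem[6:10])), 1L)
  expect_gt(modularityScore(part), 0.4)

  part2 <- detectModules(net, seed = 1)
  expect_identical(moduleMembership(part), moduleMembership(part2))
})

test_that("candidate ranking takes top-k traffic then orders by q", {
  mem <- c(m1 = 1L, m2 = 1L, m3 = 1L, m4 = 1L, G1 = 1L, m5 = 2L)
  part <- new("ModulePartition", membership = mem, modularity = 0.1)
  traffic <- data.frame(
    node = c("m1", "m2", "m3", "m4", "G1", "m5"),
    kind = c(rep("mirna", 4), "gene", "mirna"),
    traffic = c(10, 8, 6, 1, 99, 50))
  de <- data.frame(mirna_id = c("m1", "m2", "m3", "m4", "m5"),
                   q_value = c(0.04, 0.001, 0.02, 1e-6, 1e-9))
  r <- rankCandidates(part, traffic, de, moduleId = 1, k = 3)
  # top-3 traffic in module 1 = m1, m2, m3; reordered by q
  expect_equal(r$mirna_id, c("m2", "m3", "m1"))
  expect_equal(r$rank, 1:3)
  # m5 (other module) and G1 (gene) never appear; m4 dropped by k
  expect_false(any(c("m4", "m5", "G1") %in% r$mirna_id))

  # invariance to input row order
  shuf <- sample(nrow(traffic))
  r2 <- rankCandidates(part, traffic[shuf, ], de[sample(5), ],
                       moduleId = 1, k = 3)
  expect_identical(r, r2)

  # module without miRNAs: empty ranking with a warning
  memG <- c(G1 = 1L)
  partG <- new("ModulePartition", membership = memG, modularity = 0)
  expect_warning(
    rG <- rankCandidates(partG, traffic, de, moduleId = 1),
    "no miRNA")
  expect_equal(nrow(rG), 0L)

  # independent two-column sort oracle on random inputs
  set.seed(34)
  for (i in 1:10) {
    nm <- 15
    tr <- data.frame(node = paste0("x", 1:nm), kind = "mirna",
                     traffic = sample(1:8, nm, replace = TRUE))
    dd <- data.frame(mirna_id = paste0("x", 1:nm),
                     q_value = round(runif(nm), 2))
    pp <- new("ModulePartition",
              membership = stats::setNames(rep(1L, nm), tr$node),
              modularity = 0)
    r3 <- rankCandidates(pp, tr, dd, moduleId = 1, k = 5)
    ord <- order(-tr$traffic, dd$q_value, tr$node)[1:5]
    ord <- ord[order(dd$q_value[ord], tr$node[ord])]
    expect_equal(r3$mirna_id, tr$node[ord])
  }
})
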