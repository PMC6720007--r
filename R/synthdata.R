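#' @include AllClasses.R
NULL

# The designated candidate is planted at twice the generic DE magnitude so
# the strongest effect, the densest target neighbourhood and the nominated
# miRNA coincide by construction (mirrors a hub regulator of one community).
.CANDIDATE_BOOST <- 2

.mirnaIds <- function(n) sprintf("mir-%04d", seq_len(n))
.geneIds <- function(n) sprintf("GENE%04d", seq_len(n))

#' Simulate a case/control miRNA expression experiment with ground truth
#'
#' Generates a log2-signal matrix of `nMirnas` miRNA probes plus
#' `nNegctrlProbes` negative-control probes over `nCases + nControls`
#' samples. A fraction `fracDE` of miRNAs carries a planted group-mean
#' difference of `±deLog2fcMagnitude` (random sign); one planted miRNA is
#' designated the *candidate* and receives a down-regulated effect of twice
#' that magnitude, with its true target edges concentrated in a single gene
#' community. Negative-control probes are drawn from a low-signal
#' distribution (`baselineMean - 3`), and a `detectionDropoutRate` fraction
#' of non-DE miRNAs is unexpressed — all their entries drawn from
#' sub-control-level background — emulating probes undetected on the
#' array. The returned ground truth also fixes the gene
#' community structure and true miRNA-target edges used by the other
#' generators.
#'
#' @param config a [SimulationConfig-class].
#' @param seed random seed; defaults to `config@seed`.
#' @return A list with elements `experiment` (a [MirnaExperiment-class])
#'   and `truth` (a [GroundTruth-class]).
#' @examples
#' sim <- simulateExpression(simulationConfig(nMirnas = 50, nGenes = 40,
#'                                            nCommunities = 2))
#' sim$experiment
#' sim$truth
#' @export
simulateExpression <- function(config, seed = config@seed) {
  validObject(config)
  set.seed(seed)
  nM <- config@nMirnas
  nNeg <- config@nNegctrlProbes
  n1 <- config@nCases
  n0 <- config@nControls

  mirnas <- .mirnaIds(nM)
  samples <- c(sprintf("case_%02d", seq_len(n1)),
               sprintf("ctrl_%02d", seq_len(n0)))
  group <- rep(c("case", "control"), c(n1, n0))

  nDE <- round(config@fracDE * nM)
  deIdx <- sort(sample.int(nM, nDE))
  lfc <- numeric(nM)
  if (nDE > 0) {
    lfc[deIdx] <- sample(c(-1, 1), nDE, replace = TRUE) *
      config@deLog2fcMagnitude
    candIdx <- sample(deIdx, 1L)
    lfc[candIdx] <- -.CANDIDATE_BOOST * config@deLog2fcMagnitude
    candidate <- mirnas[candIdx]
  } else {
    candidate <- character()
  }

  base <- rnorm(nM, config@baselineMean, 1)
  rowMean <- outer(base - lfc / 2, rep(1, n1 + n0)) +
    outer(lfc, c(rep(1, n1), rep(0, n0)))
  vals <- rowMean + matrix(rnorm(nM * (n1 + n0), 0, config@withinGroupSd),
                           nM, n1 + n0)
  # detection dropout: unexpressed miRNAs sit below the negative-control
  # level in every sample; planted DE miRNAs stay expressed
  nDrop <- min(round(config@detectionDropoutRate * nM), nM - nDE)
  if (nDrop > 0) {
    dropIdx <- sample(setdiff(seq_len(nM), deIdx), nDrop)
    vals[dropIdx, ] <- rnorm(nDrop * (n1 + n0), config@baselineMean - 3.5,
                             config@withinGroupSd)
  }

  neg <- matrix(rnorm(nNeg * (n1 + n0), config@baselineMean - 3,
                      config@withinGroupSd), nNeg, n1 + n0)
  mat <- rbind(vals, neg)
  rownames(mat) <- c(mirnas, sprintf("negctrl-%03d", seq_len(nNeg)))
  colnames(mat) <- samples

  expt <- MirnaExperiment(mat, group = group,
                          isNegativeControl = rep(c(FALSE, TRUE),
                                                  c(nM, nNeg)))

  genes <- .geneIds(config@nGenes)
  community <- sample(rep_len(seq_len(config@nCommunities), config@nGenes))
  names(community) <- genes

  deMirnas <- data.frame(mirna = mirnas[deIdx], log2fc = lfc[deIdx],
                         stringsAsFactors = FALSE)
  if (length(candidate)) {
    candComm <- as.integer(sample.int(config@nCommunities, 1L))
    commGenes <- genes[community == candComm]
    edges <- lapply(deMirnas$mirna, function(m) {
      if (m == candidate) {
        k <- min(2L * config@edgesPerMirna, length(commGenes))
        sample(commGenes, k)
      } else {
        sample(genes, min(config@edgesPerMirna, length(genes)))
      }
    })
    trueEdges <- data.frame(
      mirna = rep(deMirnas$mirna, lengths(edges)),
      gene = unlist(edges), stringsAsFactors = FALSE)
  } else {
    candComm <- integer()
    trueEdges <- data.frame(mirna = character(), gene = character(),
                            stringsAsFactors = FALSE)
  }

  truth <- new("GroundTruth",
               deMirnas = deMirnas,
               communityOfGene = community,
               trueEdges = trueEdges,
               serumShiftLog = qnorm(config@targetAuc) * sqrt(2) *
                 config@serumSdLog,
               candidateMirna = candidate,
               candidateCommunity = candComm)
  list(experiment = expt, truth = truth)
}

#' Simulate per-source miRNA-target prediction tables
#'
#' Each of the `nSources` sources reports every true edge independently
#' with probability `sourceAgreement` and adds decoy edges (pairs absent
#' from the truth) so that single-source support is uninformative.
#'
#' @param config a [SimulationConfig-class]; requires `nSources >= 2`.
#' @param truth a [GroundTruth-class] with populated `trueEdges`.
#' @param seed random seed; defaults to `config@seed + 1`.
#' @param decoyFrac decoy edges per source, as a fraction of the number of
#'   true edges.
#' @return Named list of `nSources` data.frames with columns `mirna`,
#'   `gene`.
#' @export
simulateTargetTables <- function(config, truth, seed = config@seed + 1L,
                                 decoyFrac = 0.5) {
  validObject(config)
  if (config@nSources < 2L)
    stop("configuration error: 'nSources' must be >= 2 (consensus undefined)",
         call. = FALSE)
  te <- truth@trueEdges
  if (!nrow(te))
    stop("'truth' has no true edges; run simulateExpression() first",
         call. = FALSE)
  set.seed(seed)
  genes <- names(truth@communityOfGene)
  trueKey <- paste(te$mirna, te$gene, sep = "\r")
  nDecoy <- round(decoyFrac * nrow(te))
  tabs <- lapply(seq_len(config@nSources), function(s) {
    keep <- runif(nrow(te)) < config@sourceAgreement
    decoys <- data.frame(mirna = character(), gene = character(),
                         stringsAsFactors = FALSE)
    if (nDecoy > 0) {
      dm <- sample(unique(te$mirna), nDecoy, replace = TRUE)
      dg <- sample(genes, nDecoy, replace = TRUE)
      ok <- !(paste(dm, dg, sep = "\r") %in% trueKey)
      decoys <- data.frame(mirna = dm[ok], gene = dg[ok],
                           stringsAsFactors = FALSE)
    }
    out <- rbind(te[keep, c("mirna", "gene")], decoys)
    out <- out[!duplicated(paste(out$mirna, out$gene, sep = "\r")), ]
    rownames(out) <- NULL
    out
  })
  names(tabs) <- sprintf("source_%d", seq_len(config@nSources))
  tabs
}

#' Simulate a planted-partition protein-protein interaction graph
#'
#' Gene pairs inside the same planted community are joined with probability
#' `pWithin`, pairs in different communities with `pBetween`; the result is
#' undirected with no self-loops and no duplicate edges.
#'
#' @param config a [SimulationConfig-class].
#' @param truth a [GroundTruth-class] with populated `communityOfGene`.
#' @param seed random seed; defaults to `config@seed + 2`.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
simulatePPI <- function(config, truth, seed = config@seed + 2L) {
  validObject(config)
  comm <- truth@communityOfGene
  if (!length(comm))
    stop("'truth' has no gene communities; run simulateExpression() first",
         call. = FALSE)
  set.seed(seed)
  genes <- names(comm)
  n <- length(genes)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- comm[idx[, 1L]] == comm[idx[, 2L]]
  p <- ifelse(same, config@pWithin, config@pBetween)
  keep <- runif(nrow(idx)) < p
  data.frame(gene_a = genes[idx[keep, 1L]],
             gene_b = genes[idx[keep, 2L]],
             stringsAsFactors = FALSE)
}

#' Simulate a gene-set collection matching the planted communities
#'
#' Emits one gene set per planted community (named `community_<k>`, equal to
#' that community's gene list) plus `nDecoySets` decoy sets drawn uniformly
#' from the gene universe, so that enrichment of a correctly recovered
#' module against its own community's set is maximal by construction.
#'
#' @param truth a [GroundTruth-class] with populated `communityOfGene`.
#' @param nDecoySets number of uniform decoy sets (may be 0).
#' @param decoySetSize size of each decoy set.
#' @param seed random seed.
#' @return Named list of character vectors (a GMT-style collection).
#' @export
simulateGeneSets <- function(truth, nDecoySets = 20L, decoySetSize = 30L,
                             seed = 1L) {
  comm <- truth@communityOfGene
  if (!length(comm))
    stop("'truth' has no gene communities; run simulateExpression() first",
         call. = FALSE)
  set.seed(seed)
  genes <- names(comm)
  ks <- sort(unique(comm))
  sets <- lapply(ks, function(k) genes[comm == k])
  names(sets) <- sprintf("community_%d", ks)
  if (nDecoySets > 0) {
    decoys <- lapply(seq_len(nDecoySets), function(j)
      sample(genes, min(decoySetSize, length(genes))))
    names(decoys) <- sprintf("decoy_%02d", seq_len(nDecoySets))
    sets <- c(sets, decoys)
  }
  sets
}

#' Simulate a two-group serum biomarker cohort calibrated to a target AUC
#'
#' Serum levels are log-normal with equal log-scale group SDs
#' (`serumSdLog`); the case/control log-mean difference is set to
#' `qnorm(targetAuc) * sqrt(2) * serumSdLog`, the binormal shift whose
#' theoretical AUC equals `targetAuc`. An aneurysm-diameter covariate,
#' positively coupled to the log level, is emitted for every subject with
#' the case distribution centred at 49 mm.
#'
#' @param config a [SimulationConfig-class].
#' @param seed random seed; defaults to `config@seed + 4`.
#' @return data.frame with columns `subject_id`, `group`, `level`,
#'   `diameter_mm`.
#' @examples
#' serum <- simulateSerum(simulationConfig(targetAuc = 0.87))
#' head(serum)
#' @export
simulateSerum <- function(config, seed = config@seed + 4L) {
  validObject(config)  # rejects targetAuc <= 0.5
  set.seed(seed)
  n1 <- config@nSerumCases
  n0 <- config@nSerumControls
  delta <- qnorm(config@targetAuc) * sqrt(2) * config@serumSdLog
  logCase <- rnorm(n1, delta, config@serumSdLog)
  logCtrl <- rnorm(n0, 0, config@serumSdLog)
  diamCase <- 49 + 6 * (logCase - delta) + rnorm(n1, 0, 3)
  diamCtrl <- 36 + 6 * logCtrl + rnorm(n0, 0, 3)
  data.frame(
    subject_id = c(sprintf("TAA_%03d", seq_len(n1)),
                   sprintf("CTRL_%03d", seq_len(n0))),
    group = rep(c("case", "control"), c(n1, n0)),
    level = exp(c(logCase, logCtrl)),
    diameter_mm = c(diamCase, diamCtrl),
    stringsAsFactors = FALSE
  )
}

#' Simulate every input of the prioritization pipeline
#'
#' Convenience wrapper running all generators with seeds derived from
#' `config@seed` (fixed offsets, so each generator is individually
#' reproducible).
#'
#' @param config a [SimulationConfig-class].
#' @return A list with elements `experiment`, `truth`, `targetTables`,
#'   `ppi`, `geneSets`, `serum` and `config`.
#' @examples
#' study <- simulateStudy(simulationConfig(nMirnas = 60, nGenes = 60,
#'                                         nCommunities = 3, seed = 7))
#' names(study)
#' @export
simulateStudy <- function(config = simulationConfig()) {
  sim <- simulateExpression(config)
  list(
    experiment = sim$experiment,
    truth = sim$truth,
    targetTables = simulateTargetTables(config, sim$truth),
    ppi = simulatePPI(config, sim$truth),
    geneSets = simulateGeneSets(sim$truth, seed = config@seed + 3L),
    serum = simulateSerum(config),
    config = config
  )
}

#' Write a simulated study to disk in the pipeline's file dialects
#'
#' Writes the expression matrix (TSV, probes in rows), sample sheet (TSV:
#' sample_id, group), one target table per source (TSV: mirna_id, gene_id),
#' the PPI edge list (TSV: gene_a, gene_b), the gene universe (one symbol
#' per line), the gene-set collection (GMT) and the biomarker table (CSV),
#' plus a `ground_truth.json` sidecar.
#'
#' @param study output of [simulateStudy()].
#' @param outdir output directory (created if missing).
#' @return Invisibly, a named character vector of written file paths.
#' @export
writeStudyBundle <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  paths <- c(
    matrix = p("expression.tsv"), samples = p("samples.tsv"),
    universe = p("universe.txt"), ppi = p("ppi.tsv"),
    gmt = p("genesets.gmt"), biomarker = p("biomarker.csv"),
    truth = p("ground_truth.json")
  )
  expt <- study$experiment
  mat <- SummarizedExperiment::assay(expt, "log2signal")
  writeExpressionMatrix(mat, paths[["matrix"]])
  utils::write.table(
    data.frame(sample_id = colnames(expt), group = sampleGroups(expt)),
    paths[["samples"]], sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in names(study$targetTables)) {
    paths[[paste0("targets_", s)]] <- p(sprintf("targets_%s.tsv", s))
    tab <- study$targetTables[[s]]
    utils::write.table(
      data.frame(mirna_id = tab$mirna, gene_id = tab$gene),
      paths[[paste0("targets_", s)]], sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  writeLines(names(study$truth@communityOfGene), paths[["universe"]])
  utils::write.table(study$ppi, paths[["ppi"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeGmt(study$geneSets, paths[["gmt"]])
  utils::write.csv(study$serum, paths[["biomarker"]], row.names = FALSE,
                   quote = FALSE)
  truth <- study$truth
  jsonlite::write_json(
    list(de_mirnas = truth@deMirnas,
         community_of_gene = as.list(truth@communityOfGene),
         true_edges = truth@trueEdges,
         serum_shift_log = truth@serumShiftLog,
         candidate_mirna = truth@candidateMirna,
         candidate_community = truth@candidateCommunity),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
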