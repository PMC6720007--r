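# miRTraffic

Network-based prioritization of candidate microRNAs and evaluation of
their circulating-biomarker potential, for case/control cohort studies of
the kind run in cardiovascular disease research (the motivating setting is
thoracic aortic aneurysm, where tissue miRNA profiles are screened for
regulators and serum levels are tested as a diagnostic marker).

The package is aimed at computational biologists who have

1. a miRNA expression matrix (log2 microarray signal) from case and
   control tissue, with negative-control probes;
2. predicted miRNA-target tables from several prediction databases;
3. a disease-associated gene list and a protein-protein interaction (PPI)
   edge list over it;
4. a gene-set collection (GMT) for biological-process enrichment;
5. per-subject circulating levels of a candidate, with clinical
   covariates,

and who want a reproducible path from (1)-(4) to a ranked candidate list,
and from (5) to a biomarker verdict. Every input can also be simulated
with known ground truth (`simulateStudy()`), so the full pipeline is
testable end to end without external data.

## The method

**Detection and differential expression.** A miRNA is *detected* in a
sample when its signal exceeds the 0.9 quantile of that sample's
negative-control probe signals; miRNAs detected in fewer than half the
samples are dropped. Per miRNA, log2 fold change is the difference of
group means of log2 signal, tested with Welch's *t* (or Mann-Whitney) and
adjusted by Benjamini-Hochberg: `q_(i) = min_{j >= i} p_(j) m / j`. A
miRNA is reported when `q < 0.05`, `|log2FC| > 0.5` and mean log2
expression `> 5`.

**Consensus targets.** A predicted miRNA-target edge is accepted when at
least 2 of the prediction sources report it, the miRNA is differentially
expressed, and the gene belongs to the disease gene universe.

**Network and traffic scores.** Consensus edges and PPI edges form one
undirected, unweighted graph. Each node's *traffic score* is its exact
betweenness centrality,

    g(v) = sum over pairs s<t of  sigma_st(v) / sigma_st,

where `sigma_st` counts shortest s-t paths and `sigma_st(v)` those
passing through `v` (endpoints excluded; Brandes' algorithm, compiled).
The graph is decomposed into modules by seeded greedy modularity
(Louvain) optimization; modules are profiled by hypergeometric
over-representation of their genes against the GMT collection, within the
disease gene universe. The user designates the module of interest (for
example, the one enriched for vessel-biology processes); among its top-10
miRNAs by traffic score, the one with the smallest q-value is the
nominated candidate.

**Biomarker evaluation.** Serum levels are compared with a Shapiro-Wilk
normality gate (t-test if both groups pass, otherwise Mann-Whitney) and a
median fold change; the ROC curve (case = positive, level above threshold
= positive) gives a trapezoidal AUC — identical to the tie-corrected
Mann-Whitney `U/(n1 n2)` — and a Youden-optimal operating point.
Spearman correlation relates levels to continuous covariates such as
aortic diameter, and cases can be split at the median covariate value.

## Worked example

```r
library(miRTraffic)

study <- simulateStudy(simulationConfig(seed = 11))
study$experiment
#> MirnaExperiment: 650 probes (50 negative-control) x 38 samples (19 case / 19 control)

de <- differentialExpression(detectionFilter(study$experiment))
sum(de$passes_cutoffs)   # 57 of 476 detected miRNAs pass the cutoffs

ces <- consensusEdges(study$targetTables,
                      universe = names(study$truth@communityOfGene),
                      mirnas = de$mirna_id[de$passes_cutoffs])
ces
#> ConsensusEdgeSet: 1343 edges (>= 2 sources), 57 miRNAs -> 388 genes

net <- buildNetwork(ces, study$ppi)
detectModules(net, seed = 11)
#> ModulePartition: 457 nodes in 8 modules (modularity 0.505)

dir <- tempfile(); writeStudyBundle(study, dir)
mf <- runPipeline(pipelineConfigFromDir(dir,
        moduleGeneset = sprintf("community_%d",
                                study$truth@candidateCommunity)))
head(read.delim(file.path(dir, "results", "candidate_ranking.tsv")), 3)
#>   mirna_id module_id traffic_score      q_value rank
#> 1 mir-0550         2      947.6763 3.373491e-13    1
#> 2 mir-0572         2     1045.0490 2.765937e-07    2
#> 3 mir-0012         2      777.8908 5.182202e-06    3
study$truth@candidateMirna   # "mir-0550" — the planted candidate is rank 1

rocAnalysis(study$serum)
#> RocResult: AUC 0.859 (28 cases vs 20 controls)
#>   Youden cutoff 2.039: sensitivity 82.1%, specificity 80.0%
compareGroups(study$serum)$fold_change   # 2.30-fold median shift
```

The ranking reads: within the user-selected module, `mir-0550` has both a
top-10 traffic score (947.7, i.e. ~948 shortest-path pair units route
through it) and the smallest q-value, so it is the nominated candidate —
and it is exactly the miRNA the simulation planted. The serum cohort
(simulated at a target AUC of 0.87) yields an empirical AUC of 0.859 with
a sensitivity/specificity trade-off chosen by the Youden index.

A command-line wrapper with `simulate`, `de`, `consensus`, `enrich`,
`biomarker` and `run` subcommands is installed at
`inst/scripts/mirnet.R`.

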