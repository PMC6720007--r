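---
title: "miRTraffic: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miRTraffic: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical machinery
behind each stage of the candidate-miRNA prioritization and biomarker
workflow: the models assumed, the tunable parameters and their defaults,
the numerical conventions, and the places where a genuine design choice
had to be made. It also spells out what the synthetic-data generator does
and does not emulate, and therefore what a passing test suite does and
does not establish about real data.

## The expression model and its filters

The tissue experiment is modelled as log2 microarray signal. For miRNA
$i$ in sample $j$,

$$x_{ij} = \mu_i + \tfrac{\delta_i}{2}\,(\pm 1)_j + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim N(0, \sigma_w^2),$$

with per-miRNA baselines $\mu_i \sim N(\mu_0, 1)$, a planted group effect
$\delta_i$ for a fraction `fracDE` of miRNAs (zero otherwise), and
within-group noise `withinGroupSd` ($\sigma_w$, default 0.5 log2 units —
the tight technical replication typical of single-channel arrays).
Defaults mirror the motivating study design: 19 cases and 19 controls,
`baselineMean` 7, planted $|\delta| = 1$ log2 unit, 10% of miRNAs
affected. One planted miRNA, the designated *candidate*, is down-regulated
at twice the generic magnitude and its target edges concentrate in a
single gene community; this makes "strongest effect", "hub of one
module" and "expected nominee" coincide by construction, so end-to-end
nomination can be scored against ground truth.

Negative-control probes are drawn from $N(\mu_0 - 3, \sigma_w)$; the
model for control-probe signal is this package's choice, since detection
filters are usually stated only as "above the negative controls". A
`detectionDropoutRate` fraction (default 0.2) of non-DE miRNAs is
*unexpressed*: all their entries come from a sub-control background
distribution, $N(\mu_0 - 3.5, \sigma_w)$. Dropout is a property of the
probe, not of single entries: arrays lose probes wholesale (a probe
family simply is not expressed in the tissue), and an entry-level
corruption model would inject gross outliers no normalized array shows
while never actually exercising a detected-in-half-the-samples rule.

`detectionFilter()` keeps a miRNA when its signal exceeds the
`negctrlQuantile` (default 0.9) quantile of the same sample's control
probes in at least `minSampleFrac` (default 0.5) of samples. The 0.9
quantile is the conservative end of common practice; it is exposed as a
parameter because the convention is lab-specific.

`differentialExpression()` uses Welch's *t* on log2 values by default.
Moderated-variance (empirical-Bayes) testing is deliberately not used:
the workflow this package implements reports plain adjusted q-values,
and with 19 + 19 samples per-miRNA variances are well estimated, so the
shrinkage would change little while making the procedure harder to
cross-check. The Mann-Whitney alternative uses the mid-rank normal
approximation with tie correction. Multiplicity is handled by
Benjamini-Hochberg; `benjaminiHochberg()` exposes the step-up procedure
directly. The three reporting cutoffs default to `q < 0.05`,
`|log2FC| > 0.5` and mean log2 expression `> 5`. The expression cutoff is
interpreted on the *log2* scale of the normalized signal — the
convention is ambiguous in the field, so `exprMin` is a parameter rather
than a constant.

Rows with zero variance are handled explicitly: identical groups give
$p = 1$, separated constant groups $p \to 0$. Multiple probes per miRNA
can be collapsed by per-sample median (`collapseProbes()`); the median is
robust to a single misbehaving probe and requires no probe-quality
weights.

## Consensus targets

`consensusEdges()` keeps a predicted miRNA-target edge when at least
`minSources` (default 2) of the prediction tables contain it, counting
duplicates within one source once. Prediction databases disagree on
species prefixes, so ids are lowercased and a leading `hsa-`/`mmu-`
prefix is stripped by default (`idNormalization = "none"` disables
this). No per-source score thresholds are applied before counting:
sources already apply their own internal cutoffs, and a second,
package-imposed threshold would make the consensus rule depend on
incommensurable score scales.

The simulated prediction tables report each true edge independently with
probability `sourceAgreement` (default 0.8) per source and add decoy
edges absent from the truth. With three sources, a true edge survives
the two-source rule with probability $3a^2(1-a) + a^3$ (0.896 at
$a = 0.8$), which the tests check against the binomial closed form.

## Network, traffic scores and modules

The combined graph is undirected and unweighted; miRNA-target and PPI
edges carry kind tags for filtering but are treated identically by the
centrality and community computations, because the prioritization
concept treats any interaction as a conduit. The *traffic score* of a
node is its exact betweenness centrality — the number of shortest-path
pairs routed through it, with ties split evenly across equal-length
paths and endpoints excluded — computed by a compiled Brandes
accumulation (each unordered pair counted once; optional normalization
by $(n-1)(n-2)/2$). By default scores are computed on the full network;
a `partition` argument computes them within each module's induced
subgraph instead, since either convention is defensible and the choice
affects hub ranking near module boundaries.

Modules come from seeded greedy multi-level modularity optimization
(Louvain, via igraph) with an exposed `resolution` parameter; module
labels are renumbered 1..M along the vertex order so a fixed seed gives
a reproducible labelling. The synthetic PPI graph is a planted-partition
model (`pWithin` 0.2 within, `pBetween` 0.005 between, 8 communities of
50 genes by default — giving within-community densities at which
modularity methods recover planted structure essentially perfectly).

Module *selection* for candidate nomination is intentionally manual: in
practice the module of interest is chosen by inspecting its enriched
biological processes, a judgment call the tool surfaces (per-module
enrichment tables) but does not automate. `runPipeline()` accepts either
an explicit `moduleId` or a `moduleGeneset` name, selecting the module
most enriched for that set; with neither, it falls back to the overall
most-enriched module containing a miRNA.

`rankCandidates()` takes the module's top `k` (default 10) miRNAs by
traffic score — ties broken by ascending q then lexicographic id, so the
ranking is a pure function of its inputs — and reorders them by
ascending q-value; rank 1 is the nominated candidate. This two-stage
rule encodes the prioritization logic: first topological importance,
then strength of differential expression.

## Enrichment

`enrichGeneSets()` is one-sided hypergeometric over-representation
(equivalently Fisher's exact test, alternative "greater"), BH-adjusted
across the tested sets. The background universe defaults to the disease
gene universe, not the genome: the gene list entering the network was
already disease-filtered, and enriching against the genome would
conflate disease association with process membership. "Non-redundant"
top processes are produced by `topNonredundant()`: greedy selection by
ascending p, skipping any term whose overlapping-gene Jaccard similarity
with an already-selected term exceeds `maxJaccard` (default 0.5 — above
it, two terms describe substantially the same genes). The Jaccard rule
is this package's operationalization; redundancy criteria in enrichment
reports are rarely stated precisely enough to copy.

## Serum biomarker model and evaluation

Serum levels are log-normal with equal log-scale group SDs
(`serumSdLog`, default 0.69):

$$\log Y \sim N(0, \sigma^2) \text{ (controls)}, \qquad
  \log Y \sim N(\delta, \sigma^2) \text{ (cases)}, \qquad
  \delta = \Phi^{-1}(\mathrm{AUC}^\*)\,\sqrt{2}\,\sigma .$$

The shift $\delta$ is calibrated so the theoretical binormal AUC equals
`targetAuc` (default 0.87). The default $\sigma = 0.69$ is chosen from
the closed form itself: at AUC\* = 0.87 it implies
$e^\delta \approx 3.0$, i.e. a three-fold median shift — the combination
of discrimination and effect size that motivates the default settings —
and circulating-miRNA levels are right-skewed with roughly this spread
on the log scale. Each subject also receives an aneurysm-diameter
covariate linear in the log level plus $N(0, 3^2)$ mm noise, cases
centred at 49 mm; the linear coupling gives Spearman-correlation
recovery a known positive sign, and the 49 mm centre makes the
median-split subgrouping reproduce a realistic cut-off. The serum cohort
defaults to 28 cases and 20 controls.

`compareGroups()` applies the Shapiro-Wilk gate at `alphaNormality`
0.05 per group (groups above 5000 go straight to the nonparametric
branch, beyond the test's range) and reports the ratio of medians as the
fold change — medians, not means, because log-normal levels make means
unrepresentative; a mean ratio is available by flag. `rocAnalysis()`
sweeps thresholds over the observed values with the conventions *case =
positive* and *level strictly above threshold = test-positive*; the
trapezoidal AUC then equals the tie-corrected Mann-Whitney
$U/(n_1 n_2)$ exactly, which the tests assert to $10^{-12}$. The
reported operating point maximizes the Youden index, with ties broken
toward higher specificity and then the higher threshold — the
conservative choice when several cutoffs are equally informative.
`subgroupByMedian()` places a case lying exactly on the median cutpoint
in the low group.

## Determinism and degenerate inputs

Every generator is a pure function of its configuration and seed;
`simulateStudy()` derives per-generator seeds by fixed offsets so each
output is individually reproducible. `runPipeline()` writes every
intermediate with stable column orders; rerunning a configuration
reproduces byte-identical outputs (checked via MD5 in the manifest).
Degenerate inputs fail early with named errors: configurations name the
offending field, stage failures name the stage (an empty DE set, for
example, aborts at the consensus stage while retaining the DE table
already written).

## Problem sizes used by the test suite

The shipped tests run the betweenness oracle on 200 random graphs of up
to 12 nodes against exhaustive shortest-path enumeration, the consensus
oracle on 100 random three-source tables, FDR control under a global
null on 200 replicates of 1000 miRNAs (19 + 19 samples), planted-effect
recovery on 200 replicates of the default 600-miRNA design, module
recovery on 20 planted-partition graphs of 120 genes in 4 communities,
the AUC/rank-sum identity on 500 tied tables, hypergeometric-vs-
permutation agreement at 10,000 draws, and end-to-end nomination on 50
simulated studies. These sizes were chosen as the smallest at which the
binomial/Monte-Carlo error of each check is well below its assertion
margin.

## What the simulation does not emulate

The generator reproduces the *statistical structure* the analysis
assumes, not the physics of the assay. It does not model probe-level
chemistry, dye or spatial artifacts, normalization pipelines, batch
structure, or correlated miRNA co-expression (miRNAs are independent
given group); prediction-source errors are independent across sources,
whereas real databases share sequence-based biases; the PPI graph is a
clean planted partition, while real interactomes have hubs and degree
heterogeneity; serum levels are exactly log-normal with equal group
variances. Consequently, a passing suite establishes that the
implementation is correct and well calibrated *under the stated models*
— it does not certify performance on arrays with strong batch effects,
on prediction sources with correlated errors, or on cohorts whose level
distributions depart from log-normality. The network-stage counts of
any particular real study additionally depend on the database snapshots
used, and are not expected to be reproduced by synthetic runs.

## Known limitations

- Betweenness is computed on the unweighted graph; prediction confidence
  and interaction evidence scores are ignored by design.
- Greedy modularity has a resolution limit; very small modules may be
  absorbed unless `resolution` is raised.
- The hypergeometric test treats genes as exchangeable; gene length or
  degree biases are not corrected.
- ROC confidence intervals (e.g. DeLong) and covariate-adjusted AUC are
  out of scope; the package reports point estimates.
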