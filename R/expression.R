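#' @include AllClasses.R
NULL

#' Detection filter against negative-control probes
#'
#' A miRNA is called detected in a sample when its signal exceeds that
#' sample's negative-control threshold, defined as the `negctrlQuantile`
#' quantile of the negative-control probe signals in the same sample. Rows
#' detected in fewer than `minSampleFrac` of samples are removed, as are
#' the negative-control rows themselves.
#'
#' @param x a [MirnaExperiment-class] containing at least one
#'   negative-control row.
#' @param minSampleFrac minimum fraction of samples in which a miRNA must
#'   be detected (default 0.5, i.e. at least half the samples).
#' @param negctrlQuantile quantile of per-sample negative-control signal
#'   used as the detection threshold (default 0.9).
#' @return A [MirnaExperiment-class] restricted to detected miRNAs.
#' @examples
#' sim <- simulateExpression(simulationConfig(nMirnas = 100))
#' detectionFilter(sim$experiment)
#' @export
detectionFilter <- function(x, minSampleFrac = 0.5, negctrlQuantile = 0.9) {
  stopifnot(is(x, "MirnaExperiment"))
  if (minSampleFrac < 0 || minSampleFrac > 1)
    stop("'minSampleFrac' must be in [0, 1]", call. = FALSE)
  neg <- isNegativeControl(x)
  if (!any(neg))
    stop("input error: no negative-control rows in the experiment",
         call. = FALSE)
  mat <- SummarizedExperiment::assay(x, "log2signal")
  thr <- apply(mat[neg, , drop = FALSE], 2L, stats::quantile,
               probs = negctrlQuantile, names = FALSE)
  above <- sweep(mat[!neg, , drop = FALSE], 2L, thr, ">")
  keep <- rowMeans(above) >= minSampleFrac
  x[which(!neg)[keep], ]
}

#' Collapse multiple probes per miRNA by median
#'
#' Arrays often carry several probes per mature miRNA; when the row
#' annotation provides a miRNA id per probe, rows are collapsed to one per
#' miRNA by the per-sample median signal.
#'
#' @param x a [MirnaExperiment-class] whose `rowData` contains `mirnaCol`.
#' @param mirnaCol name of the `rowData` column holding the miRNA id.
#' @return A [MirnaExperiment-class] with one row per miRNA
#'   (negative-control rows are kept as-is).
#' @export
collapseProbes <- function(x, mirnaCol = "mirna") {
  stopifnot(is(x, "MirnaExperiment"))
  rd <- SummarizedExperiment::rowData(x)
  if (!mirnaCol %in% names(rd))
    stop("rowData column '", mirnaCol, "' not found", call. = FALSE)
  neg <- isNegativeControl(x)
  mat <- SummarizedExperiment::assay(x, "log2signal")
  ids <- as.character(rd[[mirnaCol]])[!neg]
  sub <- mat[!neg, , drop = FALSE]
  med <- do.call(rbind, lapply(split(seq_along(ids), ids), function(i)
    apply(sub[i, , drop = FALSE], 2L, stats::median)))
  out <- rbind(med, mat[neg, , drop = FALSE])
  MirnaExperiment(out, group = sampleGroups(x),
                  isNegativeControl = rep(c(FALSE, TRUE),
                                          c(nrow(med), sum(neg))))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment: `q_i = min_{j >= rank(i)} p_(j) * m / j`, capped
#' at 1 and order-preserving.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjaminiHochberg <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop("input error: p-values must be numeric in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

# Row-wise Welch t-test from group means/variances (two-sided).
.rowWelch <- function(mat, isCase) {
  x <- mat[, isCase, drop = FALSE]
  y <- mat[, !isCase, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate zero-variance rows: identical groups -> p 1, separated -> p 0
  zero <- se2 == 0
  if (any(zero)) p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  list(p = p, lfc = m1 - m2)
}

.rowMannWhitney <- function(mat, isCase) {
  p <- apply(mat, 1L, function(v) {
    if (all(v == v[1L])) return(1)
    stats::wilcox.test(v[isCase], v[!isCase], exact = FALSE,
                       correct = TRUE)$p.value
  })
  list(p = p, lfc = rowMeans(mat[, isCase, drop = FALSE]) -
         rowMeans(mat[, !isCase, drop = FALSE]))
}

#' Differential expression of log2 signal between cases and controls
#'
#' Computes per-miRNA log2 fold change (case minus control group means of
#' log2 signal), mean expression (grand mean), a two-group p-value, and
#' Benjamini-Hochberg q-values over all tested miRNAs. A miRNA passes the
#' reporting cutoffs when `q < qMax`, `|log2fc| > fcMin` and
#' `mean_expression > exprMin` (defaults 0.05 / 0.5 / 5).
#'
#' @param x a [MirnaExperiment-class]; apply [detectionFilter()] first.
#'   Remaining negative-control rows are dropped with a message.
#' @param method `"welch_t"` (default; Welch's t on log2 values) or
#'   `"mannwhitney"` (mid-rank normal approximation with tie correction).
#' @param qMax,fcMin,exprMin the three reporting cutoffs.
#' @return data.frame with columns `mirna_id`, `mean_expression`,
#'   `log2fc`, `p_value`, `q_value`, `detected`, `passes_cutoffs`,
#'   `direction`, one row per miRNA in input order.
#' @examples
#' sim <- simulateExpression(simulationConfig(nMirnas = 100))
#' de <- differentialExpression(detectionFilter(sim$experiment))
#' head(de[order(de$q_value), ])
#' @export
differentialExpression <- function(x, method = c("welch_t", "mannwhitney"),
                                   qMax = 0.05, fcMin = 0.5, exprMin = 5) {
  stopifnot(is(x, "MirnaExperiment"))
  method <- match.arg(method)
  if (any(isNegativeControl(x))) {
    message("dropping ", sum(isNegativeControl(x)),
            " negative-control rows before testing")
    x <- x[!isNegativeControl(x), ]
  }
  grp <- sampleGroups(x)
  isCase <- grp == "case"
  if (sum(isCase) < 2L || sum(!isCase) < 2L)
    stop("input error: each group needs at least 2 samples", call. = FALSE)
  mat <- SummarizedExperiment::assay(x, "log2signal")
  res <- switch(method,
                welch_t = .rowWelch(mat, isCase),
                mannwhitney = .rowMannWhitney(mat, isCase))
  q <- benjaminiHochberg(res$p)
  meanExpr <- rowMeans(mat)
  passes <- (q < qMax) & (abs(res$lfc) > fcMin) & (meanExpr > exprMin)
  data.frame(
    mirna_id = rownames(mat),
    mean_expression = unname(meanExpr),
    log2fc = unname(res$lfc),
    p_value = unname(res$p),
    q_value = unname(q),
    detected = TRUE,
    passes_cutoffs = unname(passes),
    direction = ifelse(res$lfc > 0, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Principal component analysis of samples
#'
#' Mean-centred PCA with probes as features and samples as observations
#' (deterministic up to component sign).
#'
#' @param x a [MirnaExperiment-class] (negative-control rows excluded).
#' @param k number of components to return; at most `min(dim)`.
#' @return A list with `scores` (samples x k matrix) and
#'   `varianceExplained` (length-k fractions, non-increasing).
#' @export
expressionPCA <- function(x, k = 2L) {
  stopifnot(is(x, "MirnaExperiment"))
  x <- x[!isNegativeControl(x), ]
  mat <- SummarizedExperiment::assay(x, "log2signal")
  if (k > min(dim(mat)))
    stop("input error: 'k' exceeds the matrix dimensions", call. = FALSE)
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       varianceExplained = ve[seq_len(k)])
}
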