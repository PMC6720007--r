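#' @include AllClasses.R
NULL

.checkBiomarkerTable <- function(table) {
  need <- c("group", "level")
  if (!all(need %in% names(table)))
    stop("input error: biomarker table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!all(table$group %in% c("case", "control")))
    stop("input error: group must be 'case' or 'control'", call. = FALSE)
  if (anyNA(table$level) || any(table$level <= 0))
    stop("input error: levels must be positive", call. = FALSE)
  invisible(table)
}

#' Two-group comparison of biomarker levels with a normality gate
#'
#' Shapiro-Wilk normality testing of each group precedes the comparison:
#' when both groups are compatible with normality at `alphaNormality` the
#' groups are compared by t-test, otherwise by the Mann-Whitney test
#' (mid-rank normal approximation with tie correction). For groups larger
#' than 5000 (beyond the Shapiro-Wilk range) the nonparametric branch is
#' used. The fold change is the ratio of group medians (case/control);
#' a mean ratio is available via `foldChange = "mean"`.
#'
#' @param table data.frame with columns `group` (`"case"`/`"control"`) and
#'   `level` (positive); at least 3 subjects per group.
#' @param alphaNormality significance level of the normality gate.
#' @param foldChange `"median"` (default) or `"mean"`.
#' @return A list with `test` (`"t"` or `"mannwhitney"`), `statistic`,
#'   `p_value`, `fold_change`, `median_case`, `median_control` and the two
#'   Shapiro-Wilk p-values (`NA` when the gate was skipped).
#' @examples
#' serum <- simulateSerum(simulationConfig())
#' compareGroups(serum)
#' @export
compareGroups <- function(table, alphaNormality = 0.05,
                          foldChange = c("median", "mean")) {
  .checkBiomarkerTable(table)
  foldChange <- match.arg(foldChange)
  cases <- table$level[table$group == "case"]
  ctrls <- table$level[table$group == "control"]
  if (length(cases) < 3L || length(ctrls) < 3L)
    stop("input error: need >= 3 subjects per group", call. = FALSE)
  swCase <- if (length(cases) <= 5000L) stats::shapiro.test(cases)$p.value
            else NA_real_
  swCtrl <- if (length(ctrls) <= 5000L) stats::shapiro.test(ctrls)$p.value
            else NA_real_
  normal <- !is.na(swCase) && !is.na(swCtrl) &&
    swCase > alphaNormality && swCtrl > alphaNormality
  if (normal) {
    ht <- stats::t.test(cases, ctrls)
    test <- "t"
  } else {
    ht <- stats::wilcox.test(cases, ctrls, exact = FALSE, correct = TRUE)
    test <- "mannwhitney"
  }
  fc <- if (foldChange == "median") stats::median(cases) / stats::median(ctrls)
        else mean(cases) / mean(ctrls)
  list(test = test, statistic = unname(ht$statistic),
       p_value = ht$p.value, fold_change = fc,
       median_case = stats::median(cases),
       median_control = stats::median(ctrls),
       shapiro_p_case = swCase, shapiro_p_control = swCtrl)
}

#' ROC analysis of a positive-valued biomarker
#'
#' Cases are the positive class and a level strictly above the threshold is
#' test-positive. Thresholds sweep the observed values (plus `-Inf` for the
#' all-positive corner); the AUC is the trapezoidal area, which equals the
#' tie-corrected Mann-Whitney `U / (n1 * n2)`. The reported operating point
#' maximizes the Youden index (sensitivity + specificity - 1), with ties
#' broken toward higher specificity, then the higher threshold.
#'
#' @param table data.frame with columns `group` and `level` (see
#'   [compareGroups()]).
#' @return A [RocResult-class].
#' @examples
#' serum <- simulateSerum(simulationConfig())
#' r <- rocAnalysis(serum)
#' r
#' auc(r)
#' @export
rocAnalysis <- function(table) {
  .checkBiomarkerTable(table)
  cases <- table$level[table$group == "case"]
  ctrls <- table$level[table$group == "control"]
  if (!length(cases) || !length(ctrls))
    stop("input error: both classes must be present", call. = FALSE)
  thr <- c(-Inf, sort(unique(c(cases, ctrls))))
  sens <- vapply(thr, function(t) mean(cases > t), numeric(1))
  spec <- vapply(thr, function(t) mean(ctrls <= t), numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  aucVal <- sum(diff(fpr[ord]) * (sens[ord][-1L] + sens[ord][-length(ord)]) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[spec[best] == max(spec[best])]
  best <- best[which.max(thr[best])]
  new("RocResult",
      curve = data.frame(threshold = thr, sensitivity = sens,
                         specificity = spec),
      auc = aucVal,
      youdenThreshold = thr[best],
      sensitivityAtYouden = sens[best],
      specificityAtYouden = spec[best],
      nCases = length(cases), nControls = length(ctrls))
}

#' Split cases at the median of a covariate
#'
#' The cutpoint is the median of `covariate` among cases; cases at or below
#' it form the low table, cases above it the high table (so with an odd
#' number of cases the median subject is in the low group).
#'
#' @param table biomarker data.frame.
#' @param covariate name of a numeric column present for all cases.
#' @return A list with `low`, `high` (case-only data.frames) and
#'   `cutpoint`.
#' @export
subgroupByMedian <- function(table, covariate = "diameter_mm") {
  .checkBiomarkerTable(table)
  if (!covariate %in% names(table))
    stop("input error: covariate '", covariate, "' not found", call. = FALSE)
  cases <- table[table$group == "case", , drop = FALSE]
  miss <- is.na(cases[[covariate]])
  if (any(miss)) {
    who <- if ("subject_id" %in% names(cases))
      cases$subject_id[miss] else which(miss)
    stop("input error: missing '", covariate, "' for subject(s): ",
         paste(who, collapse = ", "), call. = FALSE)
  }
  cutpoint <- stats::median(cases[[covariate]])
  list(low = cases[cases[[covariate]] <= cutpoint, , drop = FALSE],
       high = cases[cases[[covariate]] > cutpoint, , drop = FALSE],
       cutpoint = cutpoint)
}

#' Spearman correlation of biomarker level with a covariate
#'
#' Mid-rank Spearman correlation with the t-approximation p-value.
#'
#' @param table biomarker data.frame.
#' @param covariate name of a numeric column.
#' @param group optional group restriction (`"case"`/`"control"`).
#' @return A list with `rho`, `p_value` and `n`.
#' @export
correlateCovariate <- function(table, covariate = "diameter_mm",
                               group = NULL) {
  .checkBiomarkerTable(table)
  if (!covariate %in% names(table))
    stop("input error: covariate '", covariate, "' not found", call. = FALSE)
  if (!is.null(group)) table <- table[table$group %in% group, , drop = FALSE]
  ok <- !is.na(table$level) & !is.na(table[[covariate]])
  x <- table$level[ok]; y <- table[[covariate]][ok]
  if (length(x) < 4L)
    stop("input error: need >= 4 paired observations", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("input error: constant input, Spearman rho undefined",
         call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
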