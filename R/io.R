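#' @include AllClasses.R
NULL

#' Write an expression matrix as TSV
#'
#' Probes in rows (first column `probe_id`), samples in columns.
#'
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeExpressionMatrix <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix and sample sheet into a MirnaExperiment
#'
#' Expects the dialect written by [writeStudyBundle()]: a TSV matrix with
#' probes in rows (first column the probe id, header the sample ids) and a
#' TSV sample sheet with columns `sample_id` and `group`. Probe ids
#' matching `negctrlPattern` are flagged as negative-control rows.
#'
#' @param matrixPath path to the matrix TSV.
#' @param samplesPath path to the sample sheet TSV.
#' @param negctrlPattern regular expression identifying control probes.
#' @return A [MirnaExperiment-class].
#' @export
readExpressionMatrix <- function(matrixPath, samplesPath,
                                 negctrlPattern = "^negctrl") {
  tab <- utils::read.delim(matrixPath, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("input error: matrix file needs a probe id column plus samples",
         call. = FALSE)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(mat))
    stop("input error: non-numeric values in the expression matrix",
         call. = FALSE)
  rownames(mat) <- as.character(tab[[1L]])
  sheet <- utils::read.delim(samplesPath, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(sheet)))
    stop("input error: sample sheet needs columns sample_id, group",
         call. = FALSE)
  missing <- setdiff(colnames(mat), sheet$sample_id)
  if (length(missing))
    stop("input error: samples without a group label: ",
         paste(missing, collapse = ", "), call. = FALSE)
  grp <- sheet$group[match(colnames(mat), sheet$sample_id)]
  MirnaExperiment(mat, group = grp,
                  isNegativeControl = grepl(negctrlPattern, rownames(mat)))
}

#' Read a GEO series-matrix expression table
#'
#' Parses the series-matrix TSV layout: metadata lines prefixed `!`, with
#' the expression table between `!series_matrix_table_begin` and
#' `!series_matrix_table_end`. Returns the numeric matrix (probes x
#' samples); `!Sample_title` and `!Sample_geo_accession` lines, when
#' present, are attached as attributes `sampleTitle` / `sampleAccession`.
#'
#' @param path path to an (uncompressed) series-matrix file.
#' @return Numeric matrix with probe ids as row names.
#' @export
readGeoSeriesMatrix <- function(path) {
  lines <- readLines(path)
  b <- grep("^!series_matrix_table_begin", lines)
  e <- grep("^!series_matrix_table_end", lines)
  if (length(b) != 1L || length(e) != 1L || e <= b + 1L)
    stop("input error: series matrix table delimiters not found",
         call. = FALSE)
  tab <- utils::read.delim(text = lines[(b + 1L):(e - 1L)],
                           check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(mat) <- gsub('^"|"$', "", as.character(tab[[1L]]))
  colnames(mat) <- gsub('^"|"$', "", colnames(mat))
  grab <- function(tag) {
    ln <- grep(paste0("^!", tag, "\t"), lines, value = TRUE)
    if (!length(ln)) return(NULL)
    gsub('^"|"$', "", strsplit(ln[1L], "\t", fixed = TRUE)[[1L]][-1L])
  }
  attr(mat, "sampleTitle") <- grab("Sample_title")
  attr(mat, "sampleAccession") <- grab("Sample_geo_accession")
  mat
}

#' Read a per-source miRNA-target prediction table
#'
#' TSV whose first two columns are the miRNA and gene id; any additional
#' columns (e.g. prediction scores) are ignored.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `mirna`, `gene`.
#' @export
readTargetTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("input error: target table '", path, "' needs >= 2 columns",
         call. = FALSE)
  data.frame(mirna = as.character(tab[[1L]]), gene = as.character(tab[[2L]]),
             stringsAsFactors = FALSE)
}

#' Read a protein-protein interaction edge list
#'
#' TSV whose first two columns are interacting gene ids; a third column,
#' if present, triggers a dialect warning and is ignored.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
readPpiTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("input error: PPI file '", path, "' needs >= 2 columns",
         call. = FALSE)
  if (ncol(tab) > 2L)
    warning("PPI file has ", ncol(tab),
            " columns; columns beyond the first two are ignored")
  data.frame(gene_a = as.character(tab[[1L]]),
             gene_b = as.character(tab[[2L]]), stringsAsFactors = FALSE)
}

#' Read a gene universe (one symbol per line)
#'
#' @param path path to the text file.
#' @param aliasMap optional two-column data.frame or path to a TSV mapping
#'   alias -> preferred symbol, applied to the universe.
#' @return Character vector of unique gene ids.
#' @export
readGeneUniverse <- function(path, aliasMap = NULL) {
  ids <- trimws(readLines(path))
  ids <- ids[nzchar(ids)]
  if (!length(ids))
    stop("input error: empty gene universe file", call. = FALSE)
  if (!is.null(aliasMap)) {
    if (is.character(aliasMap))
      aliasMap <- utils::read.delim(aliasMap, header = FALSE,
                                    stringsAsFactors = FALSE)
    hit <- match(ids, aliasMap[[1L]])
    ids[!is.na(hit)] <- aliasMap[[2L]][hit[!is.na(hit)]]
  }
  unique(ids)
}

#' Read a per-subject biomarker table (CSV)
#'
#' Expected columns: `subject_id`, `group`, `level`, plus any covariates
#' (e.g. `diameter_mm`).
#'
#' @param path path to the CSV file.
#' @return data.frame.
#' @export
readBiomarkerTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  .checkBiomarkerTable(tab)
}

#' Write a differential-expression table as TSV
#'
#' Stable column order: `mirna_id`, `mean_expression`, `log2fc`,
#' `p_value`, `q_value`, `detected`, `passes_cutoffs`, `direction`.
#'
#' @param de data.frame from [differentialExpression()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeDETable <- function(de, path) {
  cols <- c("mirna_id", "mean_expression", "log2fc", "p_value", "q_value",
            "detected", "passes_cutoffs", "direction")
  utils::write.table(de[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
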