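#' @include AllClasses.R
NULL

#' Read a GMT gene-set collection
#'
#' Standard tab format: set name, description, then tab-separated members.
#'
#' @param path path to a `.gmt` file.
#' @return Named list of character vectors; descriptions kept in attribute
#'   `"descriptions"`.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("input error: GMT line ", short[1L],
         " has fewer than 3 fields", call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "descriptions") <- vapply(parts, `[[`, character(1), 2L)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional per-set description (defaults to `"na"`).
#' @return Invisibly, `path`.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in a query gene list with
#' the one-sided hypergeometric upper-tail probability (equivalently
#' Fisher's exact test, alternative "greater"), followed by
#' Benjamini-Hochberg adjustment across all tested sets. Set members
#' outside the universe are ignored; query genes outside the universe are
#' dropped with a warning.
#'
#' @param query character vector of gene ids.
#' @param collection named list of gene sets (e.g. from [readGmt()]).
#' @param universe character vector defining the background.
#' @return data.frame sorted by ascending p with columns `term`,
#'   `overlap`, `set_size`, `query_size`, `universe_size`, `p`, `q`,
#'   `genes` (comma-joined overlapping ids).
#' @examples
#' enrichGeneSets(c("a", "b", "c"),
#'                list(s1 = c("a", "b"), s2 = c("d", "e")),
#'                universe = letters[1:10])
#' @export
enrichGeneSets <- function(query, collection, universe) {
  if (!length(universe))
    stop("input error: empty universe", call. = FALSE)
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (!length(query))
    stop("input error: empty query after universe filtering", call. = FALSE)
  N <- length(universe)
  qn <- length(query)
  rows <- lapply(names(collection), function(term) {
    members <- intersect(unique(collection[[term]]), universe)
    ov <- intersect(query, members)
    m <- length(members)
    p <- if (m == 0L) 1 else
      stats::phyper(length(ov) - 1L, m, N - m, qn, lower.tail = FALSE)
    data.frame(term = term, overlap = length(ov), set_size = m,
               query_size = qn, universe_size = N, p = p,
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- benjaminiHochberg(res$p)
  res <- res[order(res$p, res$term),
             c("term", "overlap", "set_size", "query_size",
               "universe_size", "p", "q", "genes")]
  rownames(res) <- NULL
  res
}

.jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Top non-redundant enriched terms
#'
#' Greedy selection by ascending p-value, skipping any term whose
#' overlapping-gene Jaccard similarity with an already selected term
#' exceeds `maxJaccard`; stops after `n` terms. With `maxJaccard = 1` this
#' is simply the top-n by p.
#'
#' @param result data.frame from [enrichGeneSets()].
#' @param n maximum number of terms (default 5).
#' @param maxJaccard redundancy threshold in `[0, 1]` (default 0.5).
#' @return The selected rows of `result`, in selection order.
#' @export
topNonredundant <- function(result, n = 5L, maxJaccard = 0.5) {
  if (!nrow(result))
    stop("input error: empty enrichment result", call. = FALSE)
  ord <- order(result$p, result$term)
  genes <- strsplit(result$genes, ",", fixed = TRUE)
  chosen <- integer()
  for (i in ord) {
    if (length(chosen) >= n) break
    redundant <- any(vapply(chosen, function(j)
      .jaccard(genes[[i]], genes[[j]]) > maxJaccard, logical(1)))
    if (!redundant) chosen <- c(chosen, i)
  }
  out <- result[chosen, , drop = FALSE]
  rownames(out) <- NULL
  out
}
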