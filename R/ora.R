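# Over-representation analysis: one-sided hypergeometric tests of gene
# lists against GMT gene sets, BH-adjusted across the tested terms.

#' Read a GMT gene-set file
#'
#' Standard dialect: one term per line, tab-separated as
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate member ids
#' within a term are stored once; empty lines are skipped; a line with
#' fewer than three fields is a parse error naming the line number.
#'
#' @param path Path to the GMT file.
#' @return A named list (term_id -> list with `term_id`, `term_name`,
#'   `genes`), class `gene_set_annotation`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  ann <- list()
  for (ln in seq_along(lines)) {
    if (!nzchar(trimws(lines[ln]))) next
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stopf("%s: line %d has %d field(s); a GMT line needs term, description and >= 1 gene",
            path, ln, length(fields))
    }
    id <- fields[1]
    if (id %in% names(ann)) stopf("%s: line %d: duplicate term id '%s'", path, ln, id)
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stopf("%s: line %d: term '%s' has no member genes", path, ln, id)
    ann[[id]] <- list(term_id = id, term_name = fields[2], genes = genes)
  }
  structure(ann, class = "gene_set_annotation")
}

#' Write a GMT gene-set file
#'
#' Inverse of [read_gmt()].
#'
#' @param ann A `gene_set_annotation` (or list in the same shape).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(ann, path) {
  lines <- vapply(ann, function(t) {
    paste(c(t$term_id, t$term_name, t$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation test
#'
#' For each term, counts the query hits `k` among the term's members within
#' the universe (`K` members, universe size `N`, query size `n`) and
#' computes the upper-tail probability P(X >= k) of the hypergeometric
#' distribution, BH-adjusted across all tested terms of the run. Annotation
#' genes outside the universe are dropped before counting; terms with no
#' member left in the universe (or outside the size filter) are not tested.
#'
#' @param query Character vector of query gene ids (must be a subset of
#'   `universe`).
#' @param universe Character vector of background gene ids.
#' @param ann A `gene_set_annotation` from [read_gmt()].
#' @param alpha Significance threshold for the `significant` flag
#'   (default 0.05).
#' @param min_size,max_size Term-size filter applied to `K` after
#'   intersection with the universe (defaults 1, Inf).
#' @return Data frame with columns `term_id`, `term_name`, `k`, `K`, `n`,
#'   `N`, `gene_ratio`, `p`, `padj`, `significant`, `hits`.
#' @export
enrich <- function(query, universe, ann, alpha = 0.05,
                   min_size = 1L, max_size = Inf) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stopf("query gene(s) not in the universe: %s%s",
          paste(utils::head(outside, 5), collapse = ", "),
          if (length(outside) > 5) sprintf(" (+%d more)", length(outside) - 5) else "")
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(ann, function(t) {
    members <- intersect(t$genes, universe)
    K <- length(members)
    if (K < max(1L, min_size) || K > max_size) return(NULL)
    hits <- intersect(query, members)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = t$term_id, term_name = t$term_name,
               k = k, K = K, n = n, N = N,
               gene_ratio = if (n > 0) k / n else NA_real_,
               p = p, hits = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), gene_ratio = numeric(), p = numeric(),
                      padj = numeric(), significant = logical(),
                      hits = character(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$padj <- adjust_bh(out$p)
  out$significant <- out$padj < alpha
  out[, c("term_id", "term_name", "k", "K", "n", "N", "gene_ratio",
          "p", "padj", "significant", "hits")]
}

#' Top-ranked enrichment terms
#'
#' Sorted by adjusted p-value ascending, ties broken by raw p-value then
#' term id (lexicographic), truncated to `k` rows. The deterministic
#' tie-break makes top-K overlap counts reproducible.
#'
#' @param results Data frame from [enrich()].
#' @param k Number of terms to keep (> 0; default 50).
#' @return The ranked, truncated data frame.
#' @export
top_terms <- function(results, k = 50L) {
  if (k <= 0) stopf("k must be positive")
  ord <- order(results$padj, results$p, results$term_id)
  utils::head(results[ord, , drop = FALSE], k)
}
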