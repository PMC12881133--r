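# Concordance module: compare two thresholded DEG tables by overlap,
# directionality quadrants, agreement percentage, rank correlation of log2
# fold changes, and top-K enrichment-term overlap.

#' Construct a thresholded DEG table
#'
#' Applies the shared significance thresholds (padj < `alpha`,
#' |log2FC| > `lfc_threshold`, strict) and keeps only the passing genes,
#' with their direction. Sub-threshold rows are dropped; the number of
#' input rows is kept as attribute `n_input`.
#'
#' @param df Data frame with columns `gene_id`, `log2fc`, `padj`.
#' @param lfc_threshold,alpha Thresholds (defaults 1, 0.05).
#' @return Data frame of class `deg_table` with columns `gene_id`,
#'   `log2fc`, `padj`, `direction` (`"up"`/`"down"`).
#' @export
deg_table <- function(df, lfc_threshold = 1, alpha = 0.05) {
  needed <- c("gene_id", "log2fc", "padj")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stopf("DEG table is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) {
    stopf("DEG table: duplicate gene id '%s'",
          df$gene_id[duplicated(df$gene_id)][1])
  }
  pa <- df$padj
  if (any(!is.na(pa) & (pa < 0 | pa > 1))) {
    stopf("DEG table: padj outside [0, 1]")
  }
  keep <- !is.na(df$log2fc) & !is.na(pa) & pa < alpha & abs(df$log2fc) > lfc_threshold
  out <- df[keep, needed, drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  attr(out, "n_input") <- nrow(df)
  attr(out, "thresholds") <- c(lfc_threshold = lfc_threshold, alpha = alpha)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Overlap between two DEG sets
#'
#' @param a,b `deg_table` objects (or data frames with unique `gene_id`).
#' @return List with `n_a`, `n_b`, `n_shared` and the shared gene ids.
#' @export
overlap_degs <- function(a, b) {
  if (anyDuplicated(a$gene_id) || anyDuplicated(b$gene_id)) {
    stopf("overlap_degs: duplicate gene ids in input")
  }
  shared <- intersect(a$gene_id, b$gene_id)
  list(n_a = nrow(a), n_b = nrow(b), n_shared = length(shared),
       shared = shared)
}

#' Directionality quadrants and agreement percentage
#'
#' Splits the shared DEGs into the four directionality quadrants (up-up,
#' down-down, up-down, down-up, first table's direction first) and computes
#' the directional agreement 100 * (up_up + down_down) / n_shared. With no
#' shared gene the agreement is undefined and reported as NA with a
#' warning.
#'
#' @param a,b `deg_table` objects.
#' @param shared Optional character vector of shared ids (computed if
#'   NULL).
#' @return List with `quadrants` (named integer vector), `n_shared`,
#'   `agreement_pct` (full precision) and `agreement_pct_1dp` (rounded
#'   half-even to one decimal).
#' @export
quadrant_analysis <- function(a, b, shared = NULL) {
  if (is.null(shared)) shared <- intersect(a$gene_id, b$gene_id)
  da <- a$direction[match(shared, a$gene_id)]
  db <- b$direction[match(shared, b$gene_id)]
  q <- c(
    up_up = sum(da == "up" & db == "up"),
    down_down = sum(da == "down" & db == "down"),
    up_down = sum(da == "up" & db == "down"),
    down_up = sum(da == "down" & db == "up")
  )
  n <- length(shared)
  if (n == 0L) {
    warnf("quadrant_analysis: no shared DEGs; agreement undefined")
    agree <- NA_real_
  } else {
    agree <- 100 * (q[["up_up"]] + q[["down_down"]]) / n
  }
  list(quadrants = as.integer(q) |> stats::setNames(names(q)),
       n_shared = n, agreement_pct = agree,
       agreement_pct_1dp = round(agree, 1))
}

#' Spearman correlation of log2 fold changes over shared DEGs
#'
#' Rank correlation with average ranks for ties. Needs at least three
#' shared genes; a constant vector makes the correlation undefined (NA
#' with a warning).
#'
#' @param a,b `deg_table` objects.
#' @param shared Optional shared ids.
#' @return Spearman's rank correlation, or NA if undefined.
#' @export
spearman_lfc <- function(a, b, shared = NULL) {
  if (is.null(shared)) shared <- intersect(a$gene_id, b$gene_id)
  if (length(shared) < 3L) stopf("spearman_lfc needs >= 3 shared genes")
  x <- a$log2fc[match(shared, a$gene_id)]
  y <- b$log2fc[match(shared, b$gene_id)]
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warnf("spearman_lfc: constant fold-change vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Top-K enrichment-term overlap between two ranked term lists
#'
#' Counts the shared term ids within the top `k` of each list (ranked by
#' the [top_terms()] convention). If either list is shorter than `k` the
#' available prefix is used and the report is flagged as truncated.
#'
#' @param top_a,top_b Ranked term data frames (from [top_terms()]) or
#'   character vectors of ranked term ids.
#' @param k Depth of the comparison (default 50).
#' @return List with `count`, `shared_terms`, `k`, `k_a`, `k_b`,
#'   `truncated`.
#' @export
go_overlap <- function(top_a, top_b, k = 50L) {
  ids <- function(x) if (is.character(x)) x else x$term_id
  a <- ids(top_a); b <- ids(top_b)
  k_a <- min(k, length(a)); k_b <- min(k, length(b))
  truncated <- k_a < k || k_b < k
  if (truncated) {
    warnf("go_overlap: k = %d exceeds a list length; comparing top %d vs top %d",
          k, k_a, k_b)
  }
  shared <- intersect(utils::head(a, k_a), utils::head(b, k_b))
  list(count = length(shared), shared_terms = shared,
       k = k, k_a = k_a, k_b = k_b, truncated = truncated)
}

#' Full concordance report between two DEG tables
#'
#' @param a,b `deg_table` objects (e.g. the in-house sustained DEG set and
#'   an external comparator).
#' @param top_a,top_b Optional ranked enrichment-term lists for the top-K
#'   overlap component.
#' @param k Top-K depth (default 50).
#' @return List of class `concordance_report` with the overlap, quadrant,
#'   agreement, Spearman and (optionally) term-overlap components, plus a
#'   per-gene quadrant table (`gene_id`, `lfc_a`, `lfc_b`, `quadrant`).
#' @export
compare_deg_tables <- function(a, b, top_a = NULL, top_b = NULL, k = 50L) {
  ov <- overlap_degs(a, b)
  qa <- quadrant_analysis(a, b, ov$shared)
  rs <- if (ov$n_shared >= 3L) spearman_lfc(a, b, ov$shared) else NA_real_
  go <- if (!is.null(top_a) && !is.null(top_b)) go_overlap(top_a, top_b, k) else NULL
  scatter <- NULL
  if (ov$n_shared > 0L) {
    da <- a$direction[match(ov$shared, a$gene_id)]
    db <- b$direction[match(ov$shared, b$gene_id)]
    scatter <- data.frame(
      gene_id = ov$shared,
      lfc_a = a$log2fc[match(ov$shared, a$gene_id)],
      lfc_b = b$log2fc[match(ov$shared, b$gene_id)],
      quadrant = paste(da, db, sep = "_"),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(n_a = ov$n_a, n_b = ov$n_b, n_shared = ov$n_shared,
         shared = ov$shared, quadrants = qa$quadrants,
         agreement_pct = qa$agreement_pct,
         agreement_pct_1dp = qa$agreement_pct_1dp,
         spearman_rs = rs, go_overlap = go, scatter = scatter),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance: %d vs %d DEGs, %d shared\n",
              x$n_a, x$n_b, x$n_shared))
  cat(sprintf("  quadrants up-up/down-down/up-down/down-up: %s\n",
              paste(x$quadrants, collapse = "/")))
  cat(sprintf("  directional agreement: %s%%; Spearman rS = %s\n",
              format(x$agreement_pct_1dp, nsmall = 1),
              format(round(x$spearman_rs, 3))))
  if (!is.null(x$go_overlap)) {
    cat(sprintf("  top-%d term overlap: %d shared\n",
                x$go_overlap$k, x$go_overlap$count))
  }
  invisible(x)
}
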