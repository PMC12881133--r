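# Pipeline orchestrators: each stage independently runnable, plus the full
# counts -> DE -> sustained -> responder classes -> enrichment flow. These
# functions back the command-line entry point in
# `system.file("scripts", "sustainseq-pipeline.R", package = "sustainseq")`.

#' Simulate a fixture directory
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the file paths written (counts, samples, truth,
#'   manifest).
#' @export
pipeline_simulate <- function(config, out_dir) {
  sim <- simulate_experiment(config)
  paths <- write_fixture(sim, out_dir)
  write_manifest(file.path(out_dir, "manifest.json"),
                 config = unclass(config)[names(config) != "class_counts"] |>
                   c(list(class_counts = as.list(config$class_counts))),
                 seed = config$seed, inputs = unname(paths))
  invisible(c(paths, manifest = file.path(out_dir, "manifest.json")))
}

#' Classify responders from per-contrast DEG calls
#'
#' The classification stage alone: sustained status per stimulus, the
#' responder partition, the set summary, the Venn-style direction tallies
#' and the four enrichment input lists.
#'
#' @param calls Named list of DEG-call data frames with names `LPS_12h`,
#'   `LPS_24h`, `IL4_12h`, `IL4_24h` (a stimulus may be absent only as a
#'   pair).
#' @return List with `sustained` (per-stimulus data frames), `classes`,
#'   `summary`, `tallies`, `go_inputs`.
#' @export
pipeline_classify <- function(calls) {
  for (stim in .treatments) {
    have <- paste0(stim, c("_12h", "_24h")) %in% names(calls)
    if (any(have) && !all(have)) {
      stopf("classification needs both timepoints for %s", stim)
    }
  }
  needed <- as.vector(outer(.treatments, c("_12h", "_24h"), paste0))
  if (!all(needed %in% names(calls))) {
    stopf("classification needs all four contrasts (%s)",
          paste(setdiff(needed, names(calls)), collapse = ", "))
  }
  s_lps <- call_sustained(calls$LPS_12h, calls$LPS_24h, "LPS")
  s_il4 <- call_sustained(calls$IL4_12h, calls$IL4_24h, "IL4")
  classes <- classify_responders(s_lps, s_il4)
  summary <- summarize_sets(classes, s_lps, s_il4)
  tallies <- list(
    LPS = direction_tally(calls$LPS_12h, calls$LPS_24h),
    IL4 = direction_tally(calls$IL4_12h, calls$IL4_24h)
  )
  list(sustained = list(LPS = s_lps, IL4 = s_il4), classes = classes,
       summary = summary, tallies = tallies,
       go_inputs = build_go_inputs(classes))
}

#' Run the full analysis pipeline
#'
#' DE per contrast -> sustained selection -> responder classification ->
#' enrichment inputs -> over-representation analysis (if an annotation is
#' given), writing the complete result tree: `de_<contrast>.tsv`,
#' `sustained.tsv`, `responder_classes.tsv`, `set_summary.json`,
#' `go_input_<set>.txt`, `ora_<set>.tsv` and `manifest.json`.
#'
#' @param cm A [count_matrix()], or NULL to read from `counts_path` /
#'   `samples_path`.
#' @param counts_path,samples_path TSV inputs (used when `cm` is NULL).
#' @param gmt_path Optional GMT annotation; when NULL the enrichment stage
#'   is skipped with a message.
#' @param out_dir Output directory (created if missing).
#' @param lfc_threshold,alpha DEG thresholds (defaults 1, 0.05).
#' @param top_k Rows kept in the ranked enrichment reports (default 50).
#' @param sf_fallback Passed to [estimate_size_factors()].
#' @return Invisibly, a list with the DE stage (`de`), the classification
#'   stage (`classify`), the per-set enrichment results (`ora`, may be
#'   NULL) and the output paths.
#' @export
pipeline_run <- function(cm = NULL, counts_path = NULL, samples_path = NULL,
                         gmt_path = NULL, out_dir,
                         lfc_threshold = 1, alpha = 0.05, top_k = 50L,
                         sf_fallback = "error") {
  if (lfc_threshold <= 0 || alpha <= 0) stopf("thresholds must be positive")
  if (is.null(cm)) {
    if (is.null(counts_path) || is.null(samples_path)) {
      stopf("either cm or counts_path + samples_path must be given")
    }
    cm <- read_counts(counts_path, samples_path)
  }
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stopf("cannot create output directory '%s'", out_dir)
  }

  de <- run_de(cm, lfc_threshold = lfc_threshold, alpha = alpha,
               sf_fallback = sf_fallback)
  for (lbl in names(de$results)) {
    tab <- de$results[[lbl]]
    tab$direction <- de$calls[[lbl]]$direction
    write_tsv(tab, file.path(out_dir, sprintf("de_%s.tsv", lbl)))
  }

  cls <- pipeline_classify(de$calls)
  write_tsv(rbind(cls$sustained$LPS, cls$sustained$IL4),
            file.path(out_dir, "sustained.tsv"))
  write_tsv(cls$classes, file.path(out_dir, "responder_classes.tsv"))
  jsonlite::write_json(
    c(unclass(cls$summary),
      list(direction_tally = lapply(cls$tallies, as.list))),
    file.path(out_dir, "set_summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  for (set in names(cls$go_inputs)) {
    writeLines(cls$go_inputs[[set]],
               file.path(out_dir, sprintf("go_input_%s.txt", set)))
  }

  ora <- NULL
  if (!is.null(gmt_path)) {
    ann <- read_gmt(gmt_path)
    universe <- de$dispersions$gene_id[!de$dispersions$excluded]
    ora <- lapply(cls$go_inputs, function(q) {
      enrich(intersect(q, universe), universe, ann, alpha = alpha)
    })
    for (set in names(ora)) {
      write_tsv(top_terms(ora[[set]], k = max(top_k, nrow(ora[[set]]))),
                file.path(out_dir, sprintf("ora_%s.tsv", set)))
    }
  } else {
    message("no gene-set annotation given; skipping the enrichment stage")
  }

  write_manifest(
    file.path(out_dir, "manifest.json"),
    config = list(lfc_threshold = lfc_threshold, alpha = alpha,
                  top_k = top_k,
                  n_genes = nrow(cm$counts), n_samples = ncol(cm$counts)),
    seed = NULL,
    inputs = c(counts_path, samples_path, gmt_path)
  )
  invisible(list(de = de, classify = cls, ora = ora, out_dir = out_dir))
}

#' Enrichment stage on explicit gene lists
#'
#' @param query,universe Character vectors of gene ids.
#' @param gmt_path Path to the GMT annotation.
#' @param alpha Significance threshold (default 0.05).
#' @param top_k Rows in the ranked view (default 50).
#' @return List with `results` (full table) and `top` (ranked, truncated).
#' @export
pipeline_enrich <- function(query, universe, gmt_path, alpha = 0.05,
                            top_k = 50L) {
  ann <- read_gmt(gmt_path)
  results <- enrich(query, universe, ann, alpha = alpha)
  list(results = results, top = top_terms(results, k = top_k))
}

#' Concordance stage between an internal and an external DEG table
#'
#' @param a,b `deg_table` objects, or paths to DEG TSVs
#'   (`gene_id, log2fc, padj`).
#' @param top_a,top_b Optional ranked enrichment-term lists.
#' @param k Top-K depth (default 50).
#' @param out_path Optional path for `concordance.json` (full-precision
#'   values; the scatter table goes to a sibling
#'   `concordance_scatter.tsv`).
#' @param lfc_threshold,alpha Thresholds applied when reading from paths.
#' @return The [compare_deg_tables()] report.
#' @export
pipeline_compare <- function(a, b, top_a = NULL, top_b = NULL, k = 50L,
                             out_path = NULL, lfc_threshold = 1,
                             alpha = 0.05) {
  if (is.character(a)) a <- read_deg_table(a, lfc_threshold, alpha)
  if (is.character(b)) b <- read_deg_table(b, lfc_threshold, alpha)
  report <- compare_deg_tables(a, b, top_a = top_a, top_b = top_b, k = k)
  if (!is.null(out_path)) {
    out <- report[c("n_a", "n_b", "n_shared", "agreement_pct",
                    "agreement_pct_1dp", "spearman_rs")]
    out$quadrants <- as.list(report$quadrants)
    if (!is.null(report$go_overlap)) {
      out$go_overlap <- report$go_overlap[c("count", "shared_terms", "k",
                                            "k_a", "k_b", "truncated")]
    }
    jsonlite::write_json(out, out_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    if (!is.null(report$scatter)) {
      write_tsv(report$scatter,
                file.path(dirname(out_path), "concordance_scatter.tsv"))
    }
  }
  report
}
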