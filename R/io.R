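# Readers/writers for the pipeline's tab-separated formats, with strict
# validation. Single dialect: TSV, UTF-8, header row; gene identifiers are
# opaque strings (no case folding).

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "",
                    colClasses = "character", ...)
}

#' Read a count matrix and its sample table
#'
#' Counts TSV: first column `gene_id`, remaining columns one per sample,
#' integer cells. Sample table TSV: columns `sample_id`, `stimulus`
#' (control/LPS/IL4), `timepoint` (12/24), `replicate`. Validation failures
#' name the file and the offending cell.
#'
#' @param counts_path,samples_path Paths to the two TSV files.
#' @return A validated [count_matrix()].
#' @export
read_counts <- function(counts_path, samples_path) {
  raw <- read_tsv(counts_path)
  if (names(raw)[1] != "gene_id") {
    stopf("%s: first column must be 'gene_id' (found '%s')",
          counts_path, names(raw)[1])
  }
  if (ncol(raw) < 2L) stopf("%s: no sample columns", counts_path)
  gene_id <- raw$gene_id
  if (anyDuplicated(gene_id)) {
    stopf("%s: duplicate gene id '%s'", counts_path,
          gene_id[duplicated(gene_id)][1])
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  bad <- !grepl("^[0-9]+$", vals)
  dim(bad) <- dim(vals)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stopf("%s: non-integer count '%s' at gene '%s', sample '%s'",
          counts_path, vals[idx[1], idx[2]], gene_id[idx[1]],
          colnames(vals)[idx[2]])
  }
  counts <- matrix(as.integer(vals), nrow = nrow(vals),
                   dimnames = list(gene_id, colnames(vals)))

  st <- read_tsv(samples_path)
  needed <- c("sample_id", "stimulus", "timepoint", "replicate")
  missing_cols <- setdiff(needed, names(st))
  if (length(missing_cols)) {
    stopf("%s: missing column(s): %s", samples_path,
          paste(missing_cols, collapse = ", "))
  }
  # vocabulary/consistency checks live in the count_matrix constructor;
  # re-raise with the file names attached for a usable error message
  tryCatch(
    count_matrix(counts, st[, needed]),
    error = function(e) {
      stopf("%s / %s: %s", counts_path, samples_path, conditionMessage(e))
    }
  )
}

#' Read the planted-truth table of a simulated fixture
#'
#' @param path Path to `truth.tsv` as written by [write_fixture()].
#' @return Data frame with typed columns.
#' @export
read_truth <- function(path) {
  tt <- read_tsv(path)
  needed <- c("gene_id", "label", "baseline_mean", "dispersion",
              "lfc_lps_12", "lfc_lps_24", "lfc_il4_12", "lfc_il4_24")
  missing_cols <- setdiff(needed, names(tt))
  if (length(missing_cols)) {
    stopf("%s: missing column(s): %s", path, paste(missing_cols, collapse = ", "))
  }
  for (col in needed[-(1:2)]) tt[[col]] <- as.numeric(tt[[col]])
  bad <- setdiff(unique(tt$label), gene_classes())
  if (length(bad)) stopf("%s: unknown gene class(es): %s", path,
                         paste(bad, collapse = ", "))
  tt
}

#' Read an external DEG table and threshold it
#'
#' Expects a TSV with header `gene_id`, `log2fc`, `padj` (extra columns are
#' ignored). Directions are computed with the run's thresholds; rows
#' failing them are excluded from the DEG set.
#'
#' @param path Path to the TSV.
#' @param lfc_threshold,alpha Thresholds (defaults 1, 0.05).
#' @return A [deg_table()].
#' @export
read_deg_table <- function(path, lfc_threshold = 1, alpha = 0.05) {
  df <- read_tsv(path)
  needed <- c("gene_id", "log2fc", "padj")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stopf("%s: missing column(s): %s", path, paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) {
    stopf("%s: duplicate gene id '%s'", path,
          df$gene_id[duplicated(df$gene_id)][1])
  }
  num <- function(col) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & !(df[[col]] %in% c("NA", "")))
    if (length(bad)) {
      stopf("%s: line %d, column '%s': not a number ('%s')",
            path, bad[1] + 1L, col, df[[col]][bad[1]])
    }
    x
  }
  df$log2fc <- num("log2fc")
  df$padj <- num("padj")
  if (any(!is.na(df$padj) & (df$padj < 0 | df$padj > 1))) {
    bad <- which(!is.na(df$padj) & (df$padj < 0 | df$padj > 1))[1]
    stopf("%s: line %d: padj %g outside [0, 1]", path, bad + 1L, df$padj[bad])
  }
  deg_table(df[, needed], lfc_threshold = lfc_threshold, alpha = alpha)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, seed, package version, the engine's
#' simplification notice, MD5 digests of the input files and a timestamp.
#'
#' @param path Output JSON path.
#' @param config Named list of configuration values.
#' @param seed Integer seed or NULL.
#' @param inputs Character vector of input file paths to digest.
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(path, config = list(), seed = NULL,
                           inputs = character()) {
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else {
    list()
  }
  manifest <- list(
    package = "sustainseq",
    version = as.character(utils::packageVersion("sustainseq")),
    de_engine_notice = .de_notice,
    seed = seed,
    config = config,
    input_digests = digests,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(manifest)
}
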