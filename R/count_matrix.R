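#' Construct a validated count matrix with sample annotations
#'
#' The entry point of the analysis pipeline: a genes x samples matrix of
#' non-negative integer read counts together with a sample table describing
#' the stimulation design (stimulus, timepoint, replicate).
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids) and
#'   samples in columns (colnames = sample ids).
#' @param sample_table Data frame with columns `sample_id`, `stimulus`
#'   (one of `"control"`, `"LPS"`, `"IL4"`), `timepoint` (12 or 24, hours)
#'   and `replicate` (positive integer).
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `samples`.
#' @examples
#' counts <- matrix(rpois(12, 50), nrow = 3,
#'                  dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' samples <- data.frame(sample_id = paste0("s", 1:4),
#'                       stimulus = c("control", "LPS", "control", "LPS"),
#'                       timepoint = c(12, 12, 24, 24),
#'                       replicate = 1L)
#' cm <- count_matrix(counts, samples)
#' @export
count_matrix <- function(counts, sample_table) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage <- counts
  if (is.null(rownames(storage)) || is.null(colnames(storage))) {
    stopf("count matrix must have gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(storage))) {
    stopf("duplicate gene id in count matrix: %s",
          rownames(storage)[duplicated(rownames(storage))][1])
  }
  if (anyDuplicated(colnames(storage))) {
    stopf("duplicate sample id in count matrix: %s",
          colnames(storage)[duplicated(colnames(storage))][1])
  }
  if (any(is.na(storage))) stopf("count matrix contains missing values")
  if (any(storage < 0)) stopf("count matrix contains negative values")
  if (any(storage != round(storage))) {
    bad <- which(storage != round(storage), arr.ind = TRUE)[1, ]
    stopf("non-integer count at gene '%s', sample '%s'",
          rownames(storage)[bad[1]], colnames(storage)[bad[2]])
  }
  mode(storage) <- "integer"

  st <- as.data.frame(sample_table, stringsAsFactors = FALSE)
  needed <- c("sample_id", "stimulus", "timepoint", "replicate")
  missing_cols <- setdiff(needed, names(st))
  if (length(missing_cols)) {
    stopf("sample table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  st$sample_id <- as.character(st$sample_id)
  st$stimulus <- as.character(st$stimulus)
  st$timepoint <- suppressWarnings(as.integer(st$timepoint))
  st$replicate <- suppressWarnings(as.integer(st$replicate))
  if (anyDuplicated(st$sample_id)) {
    stopf("duplicate sample id in sample table: %s",
          st$sample_id[duplicated(st$sample_id)][1])
  }
  bad_stim <- setdiff(unique(st$stimulus), .stimuli)
  if (length(bad_stim)) {
    stopf("sample table: stimulus value(s) outside {%s}: %s",
          paste(.stimuli, collapse = ", "), paste(bad_stim, collapse = ", "))
  }
  if (any(is.na(st$timepoint)) || !all(st$timepoint %in% .timepoints)) {
    bad <- unique(st$timepoint[is.na(st$timepoint) | !(st$timepoint %in% .timepoints)])
    stopf("sample table: timepoint value(s) outside {%s}: %s",
          paste(.timepoints, collapse = ", "), paste(bad, collapse = ", "))
  }
  if (any(is.na(st$replicate)) || any(st$replicate < 1L)) {
    stopf("sample table: replicate must be a positive integer")
  }

  only_counts <- setdiff(colnames(storage), st$sample_id)
  only_table <- setdiff(st$sample_id, colnames(storage))
  if (length(only_counts)) {
    stopf("sample(s) in counts but not in sample table: %s",
          paste(only_counts, collapse = ", "))
  }
  if (length(only_table)) {
    stopf("sample(s) in sample table but not in counts: %s",
          paste(only_table, collapse = ", "))
  }
  st <- st[match(colnames(storage), st$sample_id), , drop = FALSE]
  rownames(st) <- NULL

  # Each timepoint that carries treated samples needs its matched control,
  # otherwise the treatment-vs-control contrasts are undefined.
  for (tp in unique(st$timepoint[st$stimulus != "control"])) {
    if (!any(st$stimulus == "control" & st$timepoint == tp)) {
      stopf("design has treated samples at %d h but no control at %d h", tp, tp)
    }
  }

  structure(list(counts = storage, samples = st), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cond <- table(condition_label(x$samples$stimulus, x$samples$timepoint))
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(cond), as.integer(cond)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Column indices of a (stimulus, timepoint) cell of the design.
condition_samples <- function(cm, stimulus, timepoint) {
  which(cm$samples$stimulus == stimulus & cm$samples$timepoint == timepoint)
}
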