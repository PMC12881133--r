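# Synthetic-data module: negative-binomial count simulator with planted
# transcriptional programs over the 2-stimulus x 2-timepoint design.

#' Gene response classes available to the simulator
#'
#' Each class maps deterministically to a signed log2 fold-change pattern
#' over the four treated conditions (LPS 12 h, LPS 24 h, IL-4 12 h,
#' IL-4 24 h). Sustained classes are nonzero with equal sign at both
#' timepoints of their stimulus; transient classes at exactly one
#' timepoint; flip classes change sign between 12 h and 24 h (the
#' F5/Fabp3-like direction-inconsistent pattern); `none` is all-zero.
#'
#' @return Character vector of class labels.
#' @export
gene_classes <- function() rownames(.class_patterns)

# Signed effect pattern per class; multiplied by effect_lfc at simulation
# time. Columns: LPS 12h, LPS 24h, IL4 12h, IL4 24h.
.class_patterns <- matrix(
  c(
    0,  0,  0,  0,   # none
    1,  1,  0,  0,   # lps_up
    -1, -1,  0,  0,  # lps_down
    0,  0,  1,  1,   # il4_up
    0,  0, -1, -1,   # il4_down
    1,  1,  1,  1,   # common_up
    -1, -1, -1, -1,  # common_down
    1,  1, -1, -1,   # opp_lps_up_il4_down
    -1, -1,  1,  1,  # opp_il4_up_lps_down
    1,  0,  0,  0,   # transient_lps_12
    0,  1,  0,  0,   # transient_lps_24
    0,  0,  1,  0,   # transient_il4_12
    0,  0,  0,  1,   # transient_il4_24
    -1,  1,  0,  0,  # flip_lps  (down at 12 h, up at 24 h)
    0,  0,  1, -1    # flip_il4  (up at 12 h, down at 24 h)
  ),
  ncol = 4, byrow = TRUE,
  dimnames = list(
    c("none", "lps_up", "lps_down", "il4_up", "il4_down",
      "common_up", "common_down",
      "opp_lps_up_il4_down", "opp_il4_up_lps_down",
      "transient_lps_12", "transient_lps_24",
      "transient_il4_12", "transient_il4_24",
      "flip_lps", "flip_il4"),
    c("lfc_lps_12", "lfc_lps_24", "lfc_il4_12", "lfc_il4_24")
  )
)

#' Default planted-class composition
#'
#' Proportions echo the relative sizes of the responder sets reported for
#' microglial LPS/IL-4 stimulation (LPS programs several-fold larger than
#' IL-4 programs, small common and opposite sets, a handful of
#' direction-flipping genes), scaled to `n_genes`; the remainder is `none`.
#'
#' @param n_genes Total number of genes.
#' @return Named integer vector over [gene_classes()] summing to `n_genes`.
#' @export
default_class_counts <- function(n_genes) {
  prop <- c(
    lps_up = 0.060, lps_down = 0.040,
    il4_up = 0.016, il4_down = 0.012,
    common_up = 0.006, common_down = 0.006,
    opp_lps_up_il4_down = 0.004, opp_il4_up_lps_down = 0.004,
    transient_lps_12 = 0.008, transient_lps_24 = 0.008,
    transient_il4_12 = 0.008, transient_il4_24 = 0.008,
    flip_lps = 0.002, flip_il4 = 0.002
  )
  counts <- floor(prop * n_genes)
  out <- stats::setNames(integer(length(gene_classes())), gene_classes())
  out[names(counts)] <- as.integer(counts)
  out["none"] <- n_genes - sum(counts)
  if (out["none"] < 0) stopf("n_genes too small for the default class composition")
  out
}

#' Simulation configuration
#'
#' @param n_genes Number of genes.
#' @param replicates Replicates per condition (>= 2; the DE stage needs
#'   within-group variance). Default 5, the design of the emulated study.
#' @param class_counts Named integer vector over [gene_classes()]; must sum
#'   to `n_genes`. Defaults to [default_class_counts()].
#' @param effect_lfc Planted absolute log2 fold change for responder
#'   classes (> 0). Default 2, well past the |log2FC| > 1 call threshold.
#' @param baseline_logmean_mu,baseline_logmean_sigma Meanlog/sdlog of the
#'   log-normal baseline expression means (natural-log scale; defaults 4, 2).
#' @param dispersion_a0,dispersion_a1 Dispersion trend alpha = a0/mu + a1
#'   (defaults 3, 0.05); must give alpha > 0.
#' @param libsize_sigma Sdlog of log-normal per-sample depth factors
#'   (default 0.2).
#' @param seed Integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes,
                       replicates = 5L,
                       class_counts = NULL,
                       effect_lfc = 2,
                       baseline_logmean_mu = 4,
                       baseline_logmean_sigma = 2,
                       dispersion_a0 = 3,
                       dispersion_a1 = 0.05,
                       libsize_sigma = 0.2,
                       seed = 1L) {
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 1L) stopf("n_genes must be a positive integer")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 2L) {
    stopf("replicates must be >= 2 (the DE stage needs within-group variance)")
  }
  if (is.null(class_counts)) class_counts <- default_class_counts(n_genes)
  bad <- setdiff(names(class_counts), gene_classes())
  if (length(bad)) stopf("unknown gene class(es): %s", paste(bad, collapse = ", "))
  full <- stats::setNames(integer(length(gene_classes())), gene_classes())
  full[names(class_counts)] <- as.integer(class_counts)
  if (any(is.na(full)) || any(full < 0L)) {
    stopf("class_counts must be non-negative integers")
  }
  if (sum(full) != n_genes) {
    stopf("class_counts sum to %d but n_genes is %d", sum(full), n_genes)
  }
  if (!is.finite(effect_lfc) || effect_lfc <= 0) stopf("effect_lfc must be > 0")
  if (dispersion_a0 < 0 || dispersion_a1 < 0 || (dispersion_a0 == 0 && dispersion_a1 == 0)) {
    stopf("dispersion trend parameters must be non-negative with a0 + a1 > 0 (alpha must be positive)")
  }
  if (libsize_sigma < 0) stopf("libsize_sigma must be non-negative")
  structure(
    list(
      n_genes = n_genes, replicates = replicates, class_counts = full,
      effect_lfc = effect_lfc,
      baseline_logmean_mu = baseline_logmean_mu,
      baseline_logmean_sigma = baseline_logmean_sigma,
      dispersion_a0 = dispersion_a0, dispersion_a1 = dispersion_a1,
      libsize_sigma = libsize_sigma, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a two-stimulus, two-timepoint stimulation experiment
#'
#' Counts are drawn as K ~ NB(mean = s_j * mu_g * 2^delta, dispersion
#' alpha_g) where s_j is the per-sample depth factor, mu_g the log-normal
#' baseline mean, alpha_g = a0/mu_g + a1 the dispersion trend, and delta the
#' planted class effect for the sample's condition (0 for controls). The
#' design is six conditions (control/LPS/IL-4 at 12 h and 24 h) with
#' `replicates` samples each. Class labels are assigned to shuffled gene
#' indices so class membership is not positionally confounded. Fully
#' reproducible for a fixed seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_result` with elements `counts` (a
#'   [count_matrix()]) and `truth` (the planted-label table: gene_id, label,
#'   baseline_mean, dispersion, and the four per-condition true log2 fold
#'   changes).
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config object")
  with_seed(config$seed, {
    n <- config$n_genes
    gene_id <- sprintf("gene%0*d", nchar(n), seq_len(n))

    labels <- character(n)
    perm <- sample.int(n)
    labels[perm] <- rep(gene_classes(), config$class_counts)

    baseline <- stats::rlnorm(n, config$baseline_logmean_mu,
                              config$baseline_logmean_sigma)
    alpha <- config$dispersion_a0 / baseline + config$dispersion_a1

    design <- expand.grid(
      replicate = seq_len(config$replicates),
      stimulus = .stimuli, timepoint = .timepoints,
      stringsAsFactors = FALSE
    )[, c("stimulus", "timepoint", "replicate")]
    design$sample_id <- sprintf(
      "%s_%d", condition_label(design$stimulus, design$timepoint),
      design$replicate
    )
    m <- nrow(design)

    depth <- stats::rlnorm(m, 0, config$libsize_sigma)

    lfc_true <- .class_patterns[labels, , drop = FALSE] * config$effect_lfc
    rownames(lfc_true) <- gene_id

    delta <- matrix(0, nrow = n, ncol = m)
    for (j in seq_len(m)) {
      if (design$stimulus[j] != "control") {
        col <- sprintf("lfc_%s_%d", tolower(design$stimulus[j]), design$timepoint[j])
        delta[, j] <- lfc_true[, col]
      }
    }

    mu <- outer(baseline, depth) * 2^delta
    counts <- matrix(
      stats::rnbinom(n * m, mu = as.vector(mu), size = rep(1 / alpha, times = m)),
      nrow = n,
      dimnames = list(gene_id, design$sample_id)
    )

    cm <- count_matrix(counts, design[, c("sample_id", "stimulus", "timepoint", "replicate")])
    truth <- data.frame(
      gene_id = gene_id, label = labels,
      baseline_mean = baseline, dispersion = alpha,
      lfc_lps_12 = lfc_true[, "lfc_lps_12"],
      lfc_lps_24 = lfc_true[, "lfc_lps_24"],
      lfc_il4_12 = lfc_true[, "lfc_il4_12"],
      lfc_il4_24 = lfc_true[, "lfc_il4_24"],
      stringsAsFactors = FALSE, row.names = NULL
    )
    structure(list(counts = cm, truth = truth, config = config),
              class = "sim_result")
  })
}

#' Responder label a planted gene class should receive
#'
#' Maps each simulator class to the responder label the classifier assigns
#' when every differential-expression call is correct: sustained classes map
#' to their specific/common/opposite label, flip classes to `ambiguous`, and
#' transient or null classes to `none`. Used as the oracle for
#' truth-recovery checks.
#'
#' @param label Character vector of planted class labels.
#' @return Character vector of expected responder labels.
#' @export
expected_responder_label <- function(label) {
  map <- c(
    none = "none",
    lps_up = "lps_specific_up", lps_down = "lps_specific_down",
    il4_up = "il4_specific_up", il4_down = "il4_specific_down",
    common_up = "common_up", common_down = "common_down",
    opp_lps_up_il4_down = "opposite_lps_up_il4_down",
    opp_il4_up_lps_down = "opposite_il4_up_lps_down",
    transient_lps_12 = "none", transient_lps_24 = "none",
    transient_il4_12 = "none", transient_il4_24 = "none",
    flip_lps = "ambiguous", flip_il4 = "ambiguous"
  )
  bad <- setdiff(unique(label), names(map))
  if (length(bad)) stopf("unknown gene class(es): %s", paste(bad, collapse = ", "))
  unname(map[label])
}

#' Write a simulated experiment to a fixture directory
#'
#' Emits `counts.tsv` (gene_id + one column per sample), `samples.tsv`
#' (sample_id, stimulus, timepoint, replicate) and `truth.tsv` (planted
#' labels and effects), tab-separated with headers. Round-trips losslessly
#' through [read_counts()].
#'
#' @param sim A `sim_result` from [simulate_experiment()], or a list with
#'   elements `counts` (count_matrix) and `truth` (data frame or NULL).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named character vector of file paths written.
#' @export
write_fixture <- function(sim, dir) {
  cm <- sim$counts
  if (!inherits(cm, "count_matrix")) stopf("sim$counts must be a count_matrix")
  if (nrow(cm$counts) == 0L) stopf("refusing to write a fixture with zero genes")
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create fixture directory '%s'", dir)
  }
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  counts_df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(counts_df, paths["counts"])
  write_tsv(cm$samples, paths["samples"])
  if (!is.null(sim$truth)) {
    write_tsv(sim$truth, paths["truth"])
  } else {
    paths <- paths[c("counts", "samples")]
  }
  invisible(paths)
}
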