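# Differential-expression engine: a documented, simplified negative-binomial
# Wald pipeline. Gene-wise Cox-Reid adjusted ML dispersions, no dispersion or
# fold-change shrinkage, no independent filtering, no outlier handling;
# reproducibility of the downstream classification logic, not
# bit-compatibility with any external DE package, is the target.

.de_notice <- paste(
  "simplified NB Wald pipeline: median-of-ratios size factors,",
  "gene-wise Cox-Reid adjusted ML dispersions (no trend shrinkage),",
  "unshrunken ML log2 fold changes, BH adjustment per contrast,",
  "no independent filtering, no outlier handling"
)

.alpha_min <- 1e-8
.alpha_max <- 10

#' Median-of-ratios size factors
#'
#' s_j = median over reference genes of K_gj / geomean_g, where geomean_g is
#' the geometric mean of gene g across samples and the reference genes are
#' those with strictly positive counts in every sample. If no such gene
#' exists the function fails with a message naming the fallback; with
#' `fallback = "positive"` the median of ratios is instead taken over genes
#' positive in at least half the samples, with the geometric mean computed
#' over positive entries only (logged via [message()]).
#'
#' @param cm A [count_matrix()].
#' @param fallback `"error"` (default) or `"positive"`.
#' @return Named positive numeric vector of per-sample size factors.
#' @export
estimate_size_factors <- function(cm, fallback = c("error", "positive")) {
  fallback <- match.arg(fallback)
  counts <- cm$counts
  allpos <- rowSums(counts > 0L) == ncol(counts)
  if (any(allpos)) {
    loggeo <- rowMeans(log(counts[allpos, , drop = FALSE]))
    ratios <- counts[allpos, , drop = FALSE] / exp(loggeo)
    sf <- apply(ratios, 2, stats::median)
  } else if (fallback == "error") {
    stopf(paste(
      "no gene has strictly positive counts in every sample;",
      "rerun estimate_size_factors() with fallback = \"positive\"",
      "to use the >=50%%-positive median-of-ratios variant"
    ))
  } else {
    keep <- rowSums(counts > 0L) >= ncol(counts) / 2
    if (!any(keep)) stopf("no gene is positive in at least half the samples")
    message("size factors: falling back to genes positive in >= 50% of samples, ",
            "geometric mean over positive entries only")
    sub <- counts[keep, , drop = FALSE]
    loggeo <- apply(sub, 1, function(x) mean(log(x[x > 0L])))
    ratios <- sub / exp(loggeo)
    ratios[sub == 0L] <- NA_real_
    sf <- apply(ratios, 2, stats::median, na.rm = TRUE)
  }
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stopf("size-factor estimation produced a non-positive factor")
  }
  stats::setNames(sf, colnames(counts))
}

# Per-group quasi-Poisson fitted means given size factors: for each group k,
# m_k = sum(y) / sum(s); returns the per-sample mean vector s_j * m_k(j).
.fitted_group_means <- function(y, sf, group) {
  m <- tapply(y, group, sum) / tapply(sf, group, sum)
  as.numeric(m[group]) * sf
}

# Cox-Reid adjusted NB profile log-likelihood at dispersion alpha for a
# one-way (group-factor) design with fitted means mu.
.cr_apl <- function(alpha, y, mu, group) {
  ok <- mu > 0
  ll <- sum(stats::dnbinom(y[ok], mu = mu[ok], size = 1 / alpha, log = TRUE))
  w <- mu[ok] / (1 + alpha * mu[ok])
  sw <- tapply(w, group[ok], sum)
  sw <- sw[!is.na(sw) & sw > 0]
  ll - 0.5 * sum(log(sw))
}

#' Gene-wise negative-binomial dispersions
#'
#' Estimates the per-gene dispersion alpha (var = mu + alpha * mu^2) by
#' maximizing the Cox-Reid adjusted profile likelihood over log(alpha) in
#' [1e-8, 10], with condition-wise fitted means and a method-of-moments
#' starting value retained as fallback. Genes with all-zero counts are
#' flagged `excluded` and get no estimate.
#'
#' @param cm A [count_matrix()].
#' @param sf Size factors from [estimate_size_factors()].
#' @return Data frame with columns `gene_id`, `dispersion`, `dispersion_mom`
#'   and `excluded`.
#' @export
estimate_dispersions <- function(cm, sf) {
  counts <- cm$counts
  group <- factor(condition_label(cm$samples$stimulus, cm$samples$timepoint))
  if (any(table(group) < 2L)) {
    stopf("every design condition needs >= 2 samples to estimate dispersions")
  }
  n <- nrow(counts)
  disp <- rep(NA_real_, n)
  disp_mom <- rep(NA_real_, n)
  excluded <- rowSums(counts) == 0L
  sfv <- as.numeric(sf[colnames(counts)])
  logrange <- log(c(.alpha_min, .alpha_max))
  for (g in which(!excluded)) {
    y <- counts[g, ]
    mu <- .fitted_group_means(y, sfv, group)
    ok <- mu > 0
    mom <- sum((y[ok] - mu[ok])^2 - mu[ok]) / sum(mu[ok]^2)
    disp_mom[g] <- min(max(mom, .alpha_min), .alpha_max)
    opt <- try(
      stats::optimize(function(la) .cr_apl(exp(la), y, mu, group),
                      interval = logrange, maximum = TRUE, tol = 1e-4),
      silent = TRUE
    )
    disp[g] <- if (inherits(opt, "try-error")) disp_mom[g] else exp(opt$maximum)
  }
  data.frame(gene_id = rownames(counts), dispersion = disp,
             dispersion_mom = disp_mom, excluded = excluded,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-gene negative-binomial Wald test for one treatment-vs-control contrast
#'
#' Estimates each group's expression as the mean of size-factor-normalized
#' counts -- the exact NB maximum-likelihood group mean when size factors
#' are equal, and its scale-invariant extension otherwise (rescaling a
#' sample's column together with its size factor leaves every result
#' unchanged). The Wald statistic is the log2 ratio of group means divided
#' by its standard error from the observed Fisher information of the
#' fixed-dispersion NB group-mean model, se(log m)^2 = (1/m + alpha)/n per
#' group, with a two-sided standard-normal p-value and BH adjustment across
#' the tested genes of the contrast. Each stimulus x timepoint is tested
#' against the same-timepoint untreated control; contrasts mixing
#' timepoints are rejected. Genes with zero counts in every sample of the
#' contrast are reported with NA statistics and are not part of the BH
#' family; genes with one all-zero group have an infinite fold-change
#' estimate, an infinite standard error, and p = 1 (no shrinkage or
#' pseudocounts are applied).
#'
#' @param cm A [count_matrix()].
#' @param sf Size factors.
#' @param dispersions Data frame from [estimate_dispersions()].
#' @param stimulus `"LPS"` or `"IL4"`.
#' @param timepoint 12 or 24.
#' @param control_timepoint Timepoint of the control group; must equal
#'   `timepoint` (cross-timepoint contrasts are invalid in this design).
#' @return Data frame with columns `gene_id`, `base_mean`, `log2fc`, `se`,
#'   `wald_stat`, `p`, `padj`; attribute `contrast`.
#' @export
nb_wald_test <- function(cm, sf, dispersions, stimulus, timepoint,
                         control_timepoint = timepoint) {
  if (!stimulus %in% .treatments) {
    stopf("stimulus must be one of %s", paste(.treatments, collapse = ", "))
  }
  timepoint <- as.integer(timepoint)
  if (!timepoint %in% .timepoints) stopf("timepoint must be 12 or 24")
  if (as.integer(control_timepoint) != timepoint) {
    stopf("invalid contrast: %s at %d h vs control at %d h mixes timepoints",
          stimulus, timepoint, as.integer(control_timepoint))
  }
  treated <- condition_samples(cm, stimulus, timepoint)
  ctrl <- condition_samples(cm, "control", timepoint)
  if (!length(treated) || !length(ctrl)) {
    stopf("contrast %s vs control at %d h: a group has no samples",
          stimulus, timepoint)
  }
  idx <- c(ctrl, treated)
  y_all <- cm$counts[, idx, drop = FALSE]
  sfv <- as.numeric(sf[colnames(cm$counts)])[idx]
  is_trt <- c(rep(FALSE, length(ctrl)), rep(TRUE, length(treated)))

  alpha <- dispersions$dispersion[match(rownames(cm$counts), dispersions$gene_id)]
  n <- nrow(y_all)
  q <- sweep(y_all, 2, sfv, "/")
  base_mean <- rowMeans(q)
  m_c <- rowMeans(q[, !is_trt, drop = FALSE])
  m_t <- rowMeans(q[, is_trt, drop = FALSE])
  n_c <- sum(!is_trt)
  n_t <- sum(is_trt)
  tested <- rowSums(y_all) > 0L & !is.na(alpha)

  log2fc <- se <- wald <- p <- rep(NA_real_, n)
  log2fc[tested] <- (log(m_t[tested]) - log(m_c[tested])) / log(2)
  se[tested] <- sqrt((1 / m_c[tested] + alpha[tested]) / n_c +
                     (1 / m_t[tested] + alpha[tested]) / n_t) / log(2)
  finite <- tested & is.finite(log2fc)
  wald[finite] <- log2fc[finite] / se[finite]
  p[finite] <- 2 * stats::pnorm(-abs(wald[finite]))
  # one group all zero: infinite estimate, infinite SE, uninformative test
  onezero <- tested & !is.finite(log2fc)
  se[onezero] <- Inf
  wald[onezero] <- 0
  p[onezero] <- 1
  padj <- rep(NA_real_, n)
  padj[!is.na(p)] <- adjust_bh(p[!is.na(p)])
  res <- data.frame(
    gene_id = rownames(cm$counts), base_mean = base_mean,
    log2fc = log2fc, se = se, wald_stat = wald, p = p, padj = padj,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(res, "contrast") <- contrast_label(stimulus, timepoint)
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Wraps [stats::p.adjust()] (method `"BH"`). Missing values propagate as NA
#' (with a warning giving their count) and do not enter the adjustment
#' family.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of adjusted p-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p)) stopf("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0, 1]")
  if (any(!ok)) warnf("adjust_bh: %d missing p-value(s) propagated as NA", sum(!ok))
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Threshold differential-expression calls
#'
#' A gene is called `up` iff log2fc > `lfc_threshold` and padj < `alpha`
#' (strict inequalities), `down` symmetrically, otherwise `ns`. NA
#' statistics give `ns`.
#'
#' @param res Data frame from [nb_wald_test()].
#' @param lfc_threshold Positive log2 fold-change threshold (default 1).
#' @param alpha Adjusted-significance threshold (default 0.05).
#' @return Data frame with columns `gene_id` and `direction`; attribute
#'   `contrast` carried over.
#' @export
call_degs <- function(res, lfc_threshold = 1, alpha = 0.05) {
  if (lfc_threshold <= 0 || alpha <= 0) stopf("thresholds must be positive")
  sig <- !is.na(res$padj) & !is.na(res$log2fc) & res$padj < alpha
  direction <- ifelse(sig & res$log2fc > lfc_threshold, "up",
                      ifelse(sig & res$log2fc < -lfc_threshold, "down", "ns"))
  out <- data.frame(gene_id = res$gene_id, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrast") <- attr(res, "contrast")
  out
}

#' Run the full differential-expression stage
#'
#' Estimates size factors and dispersions once, then runs the Wald test and
#' threshold calls for every treated (stimulus, timepoint) condition present
#' in the design against its matched control.
#'
#' @param cm A [count_matrix()].
#' @param lfc_threshold,alpha Call thresholds (defaults 1, 0.05).
#' @param sf,dispersions Optional precomputed values.
#' @param sf_fallback Passed to [estimate_size_factors()].
#' @return List with elements `results` and `calls` (named by contrast, e.g.
#'   `"LPS_12h"`), `size_factors`, `dispersions`, `tested` (logical vector:
#'   gene has nonzero counts overall), and `notice` (the engine's
#'   simplification notice).
#' @export
run_de <- function(cm, lfc_threshold = 1, alpha = 0.05,
                   sf = NULL, dispersions = NULL, sf_fallback = "error") {
  if (is.null(sf)) sf <- estimate_size_factors(cm, fallback = sf_fallback)
  if (is.null(dispersions)) dispersions <- estimate_dispersions(cm, sf)
  st <- unique(cm$samples[cm$samples$stimulus != "control",
                          c("stimulus", "timepoint")])
  st <- st[order(match(st$stimulus, .treatments), st$timepoint), , drop = FALSE]
  results <- list()
  calls <- list()
  for (i in seq_len(nrow(st))) {
    lbl <- contrast_label(st$stimulus[i], st$timepoint[i])
    res <- nb_wald_test(cm, sf, dispersions, st$stimulus[i], st$timepoint[i])
    results[[lbl]] <- res
    calls[[lbl]] <- call_degs(res, lfc_threshold, alpha)
  }
  list(results = results, calls = calls, size_factors = sf,
       dispersions = dispersions,
       tested = !dispersions$excluded, notice = .de_notice)
}
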