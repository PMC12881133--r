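# Independent oracles and fixture builders used across the suite.

# --- brute-force Benjamini-Hochberg step-up ---------------------------------
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  if (n > 1) for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# --- exhaustive hypergeometric upper tail (N <= 12) -------------------------
# fraction of all size-n draws from the universe with >= k hits in the term
hyper_enum_oracle <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # term members are items 1..K
  mean(hits >= k)
}

# --- rank-then-Pearson Spearman ---------------------------------------------
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# --- independent responder-classification oracle ----------------------------
# Works from the four per-(stimulus, timepoint) directions of one gene,
# written as a plain decision table over sustained "signs".
sustained_sign_oracle <- function(d12, d24) {
  if (d12 == "ns" || d24 == "ns") return(NA_integer_)  # not sustained, no flip
  s12 <- if (d12 == "up") 1L else -1L
  s24 <- if (d24 == "up") 1L else -1L
  if (s12 == s24) s12 else 0L  # 0 marks the direction-inconsistent flip
}

responder_oracle <- function(l12, l24, i12, i24) {
  sl <- sustained_sign_oracle(l12, l24)
  si <- sustained_sign_oracle(i12, i24)
  if (is.na(sl) && is.na(si)) return("none")
  if (identical(sl, 0L) || identical(si, 0L)) {
    # a flip anywhere: common/specific membership is undecidable
    return("ambiguous")
  }
  if (!is.na(sl) && !is.na(si)) {
    if (sl == si) return(if (sl > 0) "common_up" else "common_down")
    return(if (sl > 0) "opposite_lps_up_il4_down" else "opposite_il4_up_lps_down")
  }
  if (!is.na(sl)) return(if (sl > 0) "lps_specific_up" else "lps_specific_down")
  if (si > 0) "il4_specific_up" else "il4_specific_down"
}

# --- DEG-call fixture builders ----------------------------------------------
calls_from_tuples <- function(tuples) {
  # tuples: data.frame with gene_id, l12, l24, i12, i24
  mk <- function(col) {
    data.frame(gene_id = tuples$gene_id, direction = tuples[[col]],
               stringsAsFactors = FALSE)
  }
  list(LPS_12h = mk("l12"), LPS_24h = mk("l24"),
       IL4_12h = mk("i12"), IL4_24h = mk("i24"))
}

# Membership composition matching the published microglial LPS/IL-4 set
# accounting: 882/606 sustained LPS up/down, 235/166 sustained IL-4,
# 73/75 common, 24 + 21 opposite, 3 genes flipping down->up under LPS,
# 1 gene sustained down under IL-4 but flipping up->down under LPS.
published_composition_tuples <- function(n_null = 100) {
  blocks <- list(
    list(785, "up",   "up",   "ns",   "ns"),
    list(510, "down", "down", "ns",   "ns"),
    list(141, "ns",   "ns",   "up",   "up"),
    list(66,  "ns",   "ns",   "down", "down"),
    list(73,  "up",   "up",   "up",   "up"),
    list(75,  "down", "down", "down", "down"),
    list(24,  "up",   "up",   "down", "down"),
    list(21,  "down", "down", "up",   "up"),
    list(3,   "down", "up",   "ns",   "ns"),
    list(1,   "up",   "down", "down", "down"),
    list(n_null, "ns", "ns",  "ns",   "ns")
  )
  n <- sum(vapply(blocks, function(b) b[[1]], numeric(1)))
  tuples <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    l12 = unlist(lapply(blocks, function(b) rep(b[[2]], b[[1]]))),
    l24 = unlist(lapply(blocks, function(b) rep(b[[3]], b[[1]]))),
    i12 = unlist(lapply(blocks, function(b) rep(b[[4]], b[[1]]))),
    i24 = unlist(lapply(blocks, function(b) rep(b[[5]], b[[1]]))),
    stringsAsFactors = FALSE
  )
  tuples
}

random_call_tuples <- function(n, prob_sig = 0.25) {
  dirs <- c("up", "down", "ns")
  pr <- c(prob_sig / 2, prob_sig / 2, 1 - prob_sig)
  data.frame(
    gene_id = sprintf("r%04d", seq_len(n)),
    l12 = sample(dirs, n, TRUE, pr), l24 = sample(dirs, n, TRUE, pr),
    i12 = sample(dirs, n, TRUE, pr), i24 = sample(dirs, n, TRUE, pr),
    stringsAsFactors = FALSE
  )
}

# Two thresholded DEG tables realizing given quadrant counts plus unshared
# remainders, for the concordance module.
quadrant_fixture <- function(up_up = 428, down_down = 240, up_down = 11,
                             down_up = 2, extra_a = 421, extra_b = 1928) {
  n_sh <- up_up + down_down + up_down + down_up
  shared <- sprintf("sh%04d", seq_len(n_sh))
  dir_a <- rep(c("up", "down", "up", "down"),
               c(up_up, down_down, up_down, down_up))
  dir_b <- rep(c("up", "down", "down", "up"),
               c(up_up, down_down, up_down, down_up))
  lfc <- function(d, offset) ifelse(d == "up", 1.5 + offset, -1.5 - offset)
  a <- data.frame(
    gene_id = c(shared, sprintf("a%04d", seq_len(extra_a))),
    log2fc = c(lfc(dir_a, seq_len(n_sh) / n_sh),
               rep(c(2, -2), length.out = extra_a)),
    padj = 0.001, stringsAsFactors = FALSE
  )
  b <- data.frame(
    gene_id = c(shared, sprintf("b%04d", seq_len(extra_b))),
    log2fc = c(lfc(dir_b, rev(seq_len(n_sh)) / n_sh),
               rep(c(2, -2), length.out = extra_b)),
    padj = 0.001, stringsAsFactors = FALSE
  )
  list(a = deg_table(a), b = deg_table(b))
}

# --- small count-matrix builder ---------------------------------------------
two_group_cm <- function(y_ctrl, y_trt, timepoint = 12) {
  n_c <- ncol(y_ctrl)
  n_t <- ncol(y_trt)
  counts <- cbind(y_ctrl, y_trt)
  colnames(counts) <- sprintf("s%02d", seq_len(n_c + n_t))
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  }
  st <- data.frame(
    sample_id = colnames(counts),
    stimulus = rep(c("control", "LPS"), c(n_c, n_t)),
    timepoint = timepoint,
    replicate = c(seq_len(n_c), seq_len(n_t)),
    stringsAsFactors = FALSE
  )
  count_matrix(counts, st)
}

known_disp <- function(gene_ids, alpha) {
  data.frame(gene_id = gene_ids, dispersion = alpha, excluded = FALSE,
             stringsAsFactors = FALSE)
}

unit_sf <- function(cm) {
  stats::setNames(rep(1, ncol(cm$counts)), colnames(cm$counts))
}
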