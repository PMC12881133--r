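# DE engine: normalization, dispersion estimation, Wald tests, BH, calls.

make_cm <- function(counts, stim = NULL, tp = 12) {
  n <- ncol(counts)
  if (is.null(stim)) stim <- rep(c("control", "LPS"), length.out = n)
  st <- data.frame(sample_id = colnames(counts), stimulus = stim,
                   timepoint = tp, replicate = seq_len(n))
  count_matrix(counts, st)
}

named_mat <- function(x, nrow) {
  matrix(x, nrow = nrow,
         dimnames = list(sprintf("g%03d", seq_len(nrow)),
                         sprintf("s%02d", seq_len(length(x) / nrow))))
}

test_that("size factors follow the median-of-ratios definition", {
  # identical columns -> all ones
  m <- named_mat(rep(c(5L, 10L, 20L), 4), 3)
  expect_equal(unname(estimate_size_factors(make_cm(m))), rep(1, 4))
  # column2 = 2 * column1 -> (1/sqrt(2), sqrt(2))
  m2 <- named_mat(c(4L, 10L, 30L, 8L, 20L, 60L), 3)
  expect_equal(unname(estimate_size_factors(make_cm(m2))),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # single gene (4, 16): geometric mean 8 -> (0.5, 2)
  m3 <- named_mat(c(4L, 16L), 1)
  expect_equal(unname(estimate_size_factors(make_cm(m3))), c(0.5, 2))
  # invariant under gene reordering
  set.seed(1)
  m4 <- named_mat(rnbinom(200 * 4, mu = 50, size = 5), 50)
  sf_a <- estimate_size_factors(make_cm(m4))
  sf_b <- estimate_size_factors(make_cm(m4[sample(nrow(m4)), ]))
  expect_equal(sf_a, sf_b)
})

test_that("size factors agree with an independent median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(5)
  m <- named_mat(rnbinom(200 * 6, mu = 100, size = 5), 200)
  cm <- make_cm(m)
  expect_equal(unname(estimate_size_factors(cm)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-4)
})

test_that("size factors fail loudly without all-positive genes, with a working fallback", {
  m <- named_mat(c(0L, 4L, 8L, 0L, 6L, 7L, 5L, 0L, 0L, 6L, 0L, 11L), 3)
  cm <- make_cm(m)
  expect_error(estimate_size_factors(cm), "fallback")
  expect_message(sf <- estimate_size_factors(cm, fallback = "positive"),
                 "50%")
  expect_true(all(sf > 0))
})

test_that("dispersion estimates recover the generating dispersion", {
  # Poisson data: alpha at the lower boundary
  set.seed(21)
  mp <- named_mat(rpois(300 * 50, 100), 300)
  cmp <- make_cm(mp, stim = rep(c("control", "LPS"), each = 25))
  dp <- estimate_dispersions(cmp, estimate_size_factors(cmp))
  expect_gte(mean(dp$dispersion <= 0.01), 0.95)
  # NB alpha = 0.2: median estimate in [0.15, 0.25]
  set.seed(22)
  mn <- named_mat(rnbinom(300 * 100, mu = 500, size = 5), 300)
  cmn <- make_cm(mn, stim = rep(c("control", "LPS"), each = 50))
  dn <- estimate_dispersions(cmn, estimate_size_factors(cmn))
  med <- stats::median(dn$dispersion)
  expect_gte(med, 0.15)
  expect_lte(med, 0.25)
  expect_true(all(dn$dispersion >= 1e-8 & dn$dispersion <= 10))
})

test_that("all-zero genes are flagged and excluded, not errors", {
  m <- rbind(c(5L, 9L, 7L, 5L), c(0L, 0L, 0L, 0L), c(6L, 8L, 3L, 6L))
  dimnames(m) <- list(c("g001", "g002", "g003"), sprintf("s%02d", 1:4))
  cm <- make_cm(m)
  d <- estimate_dispersions(cm, estimate_size_factors(cm))
  expect_true(d$excluded[2])
  expect_true(is.na(d$dispersion[2]))
  res <- nb_wald_test(cm, unit_sf(cm), d, "LPS", 12)
  expect_true(is.na(res$p[2]))
  calls <- call_degs(res)
  expect_identical(calls$direction[2], "ns")
})

test_that("the Wald test is calibrated on null data", {
  set.seed(31)
  n <- 2000
  m <- named_mat(rnbinom(n * 10, mu = 200, size = 1 / 0.05), n)
  cm <- make_cm(m, stim = rep(c("control", "LPS"), each = 5))
  res <- nb_wald_test(cm, unit_sf(cm), known_disp(rownames(m), 0.05), "LPS", 12)
  frac <- mean(res$p < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("a planted 4-fold change is estimated accurately and detected", {
  set.seed(33)
  ok <- 0
  for (r in 1:200) {
    y <- c(rnbinom(5, mu = 1000, size = 100), rnbinom(5, mu = 4000, size = 100))
    cm <- two_group_cm(matrix(y[1:5], 1), matrix(y[6:10], 1))
    res <- nb_wald_test(cm, unit_sf(cm), known_disp("g001", 0.01), "LPS", 12)
    if (res$log2fc > 1.6 && res$log2fc < 2.4 && res$p < 0.05) ok <- ok + 1
  }
  expect_gte(ok / 200, 0.95)
})

test_that("identical groups give zero fold change and p near one", {
  y <- matrix(c(10L, 52L, 7L, 31L), 4)
  cm <- two_group_cm(y, y)
  res <- nb_wald_test(cm, unit_sf(cm), known_disp(rownames(cm$counts), 0.1),
                      "LPS", 12)
  expect_true(all(abs(res$log2fc) < 1e-6))
  expect_true(all(res$p > 0.99))
})

test_that("swapping the contrast groups negates log2fc and keeps p", {
  set.seed(41)
  m <- named_mat(rnbinom(20 * 8, mu = 150, size = 8), 20)
  st <- data.frame(sample_id = colnames(m),
                   stimulus = rep(c("control", "LPS"), each = 4),
                   timepoint = 12, replicate = 1:8)
  cm <- make_cm(m, stim = st$stimulus)
  st_sw <- st
  st_sw$stimulus <- rev(st$stimulus)
  cm_sw <- count_matrix(m, st_sw)
  d <- known_disp(rownames(m), 0.08)
  r1 <- nb_wald_test(cm, unit_sf(cm), d, "LPS", 12)
  r2 <- nb_wald_test(cm_sw, unit_sf(cm_sw), d, "LPS", 12)
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-8)
  expect_equal(r1$p, r2$p, tolerance = 1e-8)
})

test_that("rescaling a column and its size factor leaves results unchanged", {
  set.seed(43)
  m <- named_mat(rnbinom(30 * 6, mu = 120, size = 50), 30)
  cm <- make_cm(m, stim = rep(c("control", "LPS"), each = 3))
  sf <- unit_sf(cm)
  d <- known_disp(rownames(m), 1e-8)
  r1 <- nb_wald_test(cm, sf, d, "LPS", 12)
  m2 <- m
  m2[, 1] <- m2[, 1] * 3L
  sf2 <- sf
  sf2[1] <- 3
  r2 <- nb_wald_test(make_cm(m2, stim = rep(c("control", "LPS"), each = 3)),
                     sf2, d, "LPS", 12)
  expect_equal(r1$log2fc, r2$log2fc, tolerance = 1e-6)
  expect_equal(r1$p, r2$p, tolerance = 1e-6)
})

test_that("cross-timepoint contrasts are rejected", {
  cfg <- sim_config(n_genes = 20, replicates = 2, seed = 2)
  sim <- simulate_experiment(cfg)
  sf <- unit_sf(sim$counts)
  d <- known_disp(rownames(sim$counts$counts), 0.1)
  expect_error(nb_wald_test(sim$counts, sf, d, "LPS", 12, control_timepoint = 24),
               "mixes timepoints")
})

test_that("BH adjustment matches the hand-computed step-up and the brute-force oracle", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(c(0.001, 0.5)), c(0.002, 0.5))
  expect_warning(out <- adjust_bh(c(0.01, NA, 0.5)), "1 missing")
  expect_true(is.na(out[2]))
  set.seed(51)
  for (r in 1:25) {
    p <- round(runif(sample(1:20, 1)), 3)
    q <- adjust_bh(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    # monotone non-decreasing in p
    o <- order(p)
    expect_true(all(diff(q[o]) >= 0))
  }
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH keeps the empirical FDR at the nominal level", {
  set.seed(53)
  fdrs <- numeric(200)
  for (r in 1:200) {
    n0 <- 270; n1 <- 30
    y <- c(rnbinom(n0 * 10, mu = 200, size = 20),
           rnbinom(n1 * 5, mu = 200, size = 20), rnbinom(n1 * 5, mu = 800, size = 20))
    m <- rbind(named_mat(y[1:(n0 * 10)], n0),
               cbind(matrix(y[n0 * 10 + 1:(n1 * 5)], n1),
                     matrix(y[n0 * 10 + n1 * 5 + 1:(n1 * 5)], n1)))
    rownames(m) <- sprintf("g%03d", seq_len(n0 + n1))
    colnames(m) <- sprintf("s%02d", 1:10)
    cm <- make_cm(m, stim = rep(c("control", "LPS"), each = 5))
    res <- nb_wald_test(cm, unit_sf(cm), known_disp(rownames(m), 0.05), "LPS", 12)
    disc <- which(res$padj < 0.05)
    fdrs[r] <- if (length(disc)) mean(disc <= n0) else 0
  }
  mc_se <- stats::sd(fdrs) / sqrt(length(fdrs))
  expect_lte(mean(fdrs), 0.05 + 2 * mc_se)
})

test_that("threshold calls use strict inequalities", {
  res <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                    log2fc = c(2.5, 1.0, -3.0, -1.2, NA),
                    padj = c(0.001, 0.001, 0.2, 0.01, NA))
  calls <- call_degs(res)
  expect_identical(calls$direction, c("up", "ns", "ns", "down", "ns"))
  expect_error(call_degs(res, lfc_threshold = -1), "positive")
})

test_that("run_de covers every treated condition against its matched control", {
  cfg <- sim_config(n_genes = 150, replicates = 3, seed = 8)
  sim <- simulate_experiment(cfg)
  de <- run_de(sim$counts)
  expect_setequal(names(de$results),
                  c("LPS_12h", "LPS_24h", "IL4_12h", "IL4_24h"))
  for (lbl in names(de$results)) {
    res <- de$results[[lbl]]
    tested <- !is.na(res$p)
    expect_true(all(res$padj[tested] >= res$p[tested]))
    expect_true(all(res$p[tested] >= 0 & res$p[tested] <= 1))
  }
  expect_match(de$notice, "no independent filtering")
})
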