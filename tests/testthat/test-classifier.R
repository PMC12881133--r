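# Responder classifier: sustained selection, the four-way set algebra,
# direction-inconsistency exclusions and set identities.

test_that("sustained status follows the two-timepoint definition", {
  calls12 <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                        direction = c("down", "up", "up", "ns", "down"))
  calls24 <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                        direction = c("up", "up", "ns", "ns", "down"))
  s <- call_sustained(calls12, calls24, "LPS")
  # down at 12 h then up at 24 h: the F5/Gpr137c/Gm15764 pattern
  expect_identical(s$status, c("inconsistent", "up", "not_sustained",
                               "not_sustained", "down"))
  expect_error(call_sustained(calls12, calls24[1:3, ], "LPS"), "universes differ")
})

test_that("the published set composition reproduces the printed specific counts", {
  tuples <- published_composition_tuples()
  calls <- calls_from_tuples(tuples)
  s_lps <- call_sustained(calls$LPS_12h, calls$LPS_24h, "LPS")
  s_il4 <- call_sustained(calls$IL4_12h, calls$IL4_24h, "IL4")
  expect_equal(sum(s_lps$status == "up"), 882L)
  expect_equal(sum(s_lps$status == "down"), 606L)
  expect_equal(sum(s_il4$status == "up"), 235L)
  expect_equal(sum(s_il4$status == "down"), 166L)

  classes <- classify_responders(s_lps, s_il4)
  sm <- summarize_sets(classes, s_lps, s_il4)
  expect_equal(sm$common_up, 73L)
  expect_equal(sm$common_down, 75L)
  expect_equal(sm$lps_specific_up, 809L)
  expect_equal(sm$lps_specific_down, 531L)
  expect_equal(sm$il4_specific_up, 162L)
  expect_equal(sm$il4_specific_down, 90L)
  expect_equal(sm$opposite_total, 45L)

  # the Fabp3 rule: sustained down under IL-4 but direction-inconsistent
  # under LPS is excluded from both common and specific sets
  expect_equal(sm$ambiguous_il4_down, 1L)
  expect_equal(sm$il4_specific_down,
               sm$sustained_il4_down - sm$common_down - sm$ambiguous_il4_down)

  # Venn-style tallies count each flip gene in both directions
  expect_equal(direction_tally(calls$LPS_12h, calls$LPS_24h),
               c(up = 886L, down = 610L))
  expect_equal(direction_tally(calls$IL4_12h, calls$IL4_24h),
               c(up = 235L, down = 166L))

  # opposite genes are allocated to both directional enrichment lists,
  # common genes to none
  go <- build_go_inputs(classes)
  expect_length(go$LPSup, 809L)
  expect_length(go$IL4down, 90L)
  opp <- classes$gene_id[classes$label == "opposite_lps_up_il4_down"]
  expect_length(opp, 24L)
  expect_true(all(opp %in% go$LPSup))
  expect_true(all(opp %in% go$IL4down))
  common <- classes$gene_id[classes$label %in% c("common_up", "common_down")]
  expect_false(any(common %in% unlist(go)))
})

test_that("the classifier agrees with a brute-force enumeration of all direction patterns", {
  dirs <- c("up", "down", "ns")
  grid <- expand.grid(l12 = dirs, l24 = dirs, i12 = dirs, i24 = dirs,
                      stringsAsFactors = FALSE)
  grid$gene_id <- sprintf("t%02d", seq_len(nrow(grid)))
  calls <- calls_from_tuples(grid)
  s_lps <- call_sustained(calls$LPS_12h, calls$LPS_24h, "LPS")
  s_il4 <- call_sustained(calls$IL4_12h, calls$IL4_24h, "IL4")
  classes <- classify_responders(s_lps, s_il4)
  want <- mapply(responder_oracle, grid$l12, grid$l24, grid$i12, grid$i24)
  expect_identical(classes$label, unname(want))
})

test_that("classification is a partition and the set identities hold on random inputs", {
  set.seed(61)
  for (r in 1:20) {
    tuples <- random_call_tuples(150, prob_sig = runif(1, 0.1, 0.5))
    calls <- calls_from_tuples(tuples)
    s_lps <- call_sustained(calls$LPS_12h, calls$LPS_24h, "LPS")
    s_il4 <- call_sustained(calls$IL4_12h, calls$IL4_24h, "IL4")
    classes <- classify_responders(s_lps, s_il4)
    expect_true(all(classes$label %in% responder_labels()))
    expect_equal(nrow(classes), 150L)
    sm <- summarize_sets(classes, s_lps, s_il4)
    # set identities; specific counts include the opposite genes
    expect_equal(sm$lps_specific_up,
                 sm$sustained_lps_up - sm$common_up - sm$ambiguous_lps_up)
    expect_equal(sm$lps_specific_down,
                 sm$sustained_lps_down - sm$common_down - sm$ambiguous_lps_down)
    expect_equal(sm$il4_specific_up,
                 sm$sustained_il4_up - sm$common_up - sm$ambiguous_il4_up)
    expect_equal(sm$il4_specific_down,
                 sm$sustained_il4_down - sm$common_down - sm$ambiguous_il4_down)
    # the labels partition the universe
    label_counts <- table(factor(classes$label, levels = responder_labels()))
    expect_equal(sum(label_counts), 150L)
  }
})

test_that("swapping the stimuli mirrors the specific and opposite sets", {
  set.seed(63)
  tuples <- random_call_tuples(200, prob_sig = 0.4)
  calls <- calls_from_tuples(tuples)
  s_lps <- call_sustained(calls$LPS_12h, calls$LPS_24h, "LPS")
  s_il4 <- call_sustained(calls$IL4_12h, calls$IL4_24h, "IL4")
  fwd <- classify_responders(s_lps, s_il4)
  s_lps_as_il4 <- transform(s_lps, stimulus = "IL4")
  s_il4_as_lps <- transform(s_il4, stimulus = "LPS")
  rev <- classify_responders(s_il4_as_lps, s_lps_as_il4)
  swap <- c(lps_specific_up = "il4_specific_up",
            lps_specific_down = "il4_specific_down",
            il4_specific_up = "lps_specific_up",
            il4_specific_down = "lps_specific_down",
            common_up = "common_up", common_down = "common_down",
            opposite_lps_up_il4_down = "opposite_il4_up_lps_down",
            opposite_il4_up_lps_down = "opposite_lps_up_il4_down",
            ambiguous = "ambiguous", none = "none")
  expect_identical(rev$label, unname(swap[fwd$label]))
})

test_that("planted responder programs are recovered on simulated data", {
  cfg <- sim_config(n_genes = 1200, replicates = 5, seed = 71)
  sim <- simulate_experiment(cfg)
  de <- run_de(sim$counts)
  cls <- pipeline_classify(de$calls)
  tr <- sim$truth
  got <- cls$classes$label[match(tr$gene_id, cls$classes$gene_id)]
  want <- expected_responder_label(tr$label)
  named <- c("lps_up", "il4_up", "common_up", "common_down",
             "opp_lps_up_il4_down", "opp_il4_up_lps_down")
  # well-expressed planted genes are recovered almost always; the
  # low-expression tail of the baseline distribution lacks power at n = 5
  sel <- tr$label %in% named & tr$baseline_mean >= 20
  expect_gte(mean(got[sel] == want[sel]), 0.90)
  # flip-class genes are never mistaken for common responders
  flips <- tr$label %in% c("flip_lps", "flip_il4")
  expect_false(any(got[flips] %in% c("common_up", "common_down")))
})
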