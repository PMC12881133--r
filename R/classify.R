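# Responder classifier: sustained-DEG selection and the four-way responder
# set algebra (stimulus-specific / common / opposite / ambiguous), including
# the direction-inconsistency exclusions.

.responder_labels <- c(
  "lps_specific_up", "lps_specific_down",
  "il4_specific_up", "il4_specific_down",
  "common_up", "common_down",
  "opposite_lps_up_il4_down", "opposite_il4_up_lps_down",
  "ambiguous", "none"
)

#' Responder labels used by the classifier
#' @return Character vector of the ten labels.
#' @export
responder_labels <- function() .responder_labels

.check_universe <- function(a, b, what) {
  if (anyDuplicated(a$gene_id) || anyDuplicated(b$gene_id)) {
    stopf("%s: duplicate gene ids in input", what)
  }
  if (nrow(a) != nrow(b) || !setequal(a$gene_id, b$gene_id)) {
    stopf("%s: gene universes differ between the two inputs", what)
  }
}

#' Sustained-response status per gene for one stimulus
#'
#' A gene is sustained `up` (`down`) iff it is called up (down) at both
#' 12 h and 24 h; `inconsistent` iff it is significant at both timepoints
#' with opposite directions (the F5/Gpr137c/Gm15764/Fabp3 pattern);
#' otherwise `not_sustained`.
#'
#' @param calls_12,calls_24 DEG-call data frames (columns `gene_id`,
#'   `direction`) for the same stimulus at 12 h and 24 h, covering the same
#'   gene universe.
#' @param stimulus `"LPS"` or `"IL4"`.
#' @return Data frame with columns `gene_id`, `stimulus`, `status`.
#' @export
call_sustained <- function(calls_12, calls_24, stimulus) {
  if (!stimulus %in% .treatments) {
    stopf("stimulus must be one of %s", paste(.treatments, collapse = ", "))
  }
  .check_universe(calls_12, calls_24, "call_sustained")
  ord <- calls_12$gene_id
  d12 <- calls_12$direction
  d24 <- calls_24$direction[match(ord, calls_24$gene_id)]
  ok <- c("up", "down", "ns")
  if (!all(d12 %in% ok) || !all(d24 %in% ok)) {
    stopf("call_sustained: direction must be one of up, down, ns")
  }
  status <- ifelse(
    d12 == "up" & d24 == "up", "up",
    ifelse(d12 == "down" & d24 == "down", "down",
           ifelse(d12 != "ns" & d24 != "ns", "inconsistent", "not_sustained"))
  )
  data.frame(gene_id = ord, stimulus = stimulus, status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify genes into responder sets from their sustained status
#'
#' Assigns exactly one label per gene (a partition), in this decision
#' order:
#' 1. not sustained under either stimulus -> `none`;
#' 2. sustained with the same sign under both stimuli -> `common_up` /
#'    `common_down`;
#' 3. sustained with opposite signs -> `opposite_lps_up_il4_down` /
#'    `opposite_il4_up_lps_down`;
#' 4. sustained under one stimulus and direction-inconsistent under the
#'    other -> `ambiguous` (the Fabp3 rule: excluded from both common and
#'    specific sets);
#' 5. sustained under exactly one stimulus -> that stimulus's specific
#'    label;
#' 6. direction-inconsistent under one or both stimuli, otherwise
#'    unpaired -> `ambiguous`.
#'
#' @param s_lps,s_il4 Sustained-status data frames from [call_sustained()]
#'   for LPS and IL-4, same gene universe.
#' @return Data frame with columns `gene_id` and `label`.
#' @export
classify_responders <- function(s_lps, s_il4) {
  .check_universe(s_lps, s_il4, "classify_responders")
  ord <- s_lps$gene_id
  l <- s_lps$status
  i <- s_il4$status[match(ord, s_il4$gene_id)]
  ok <- c("up", "down", "inconsistent", "not_sustained")
  if (!all(l %in% ok) || !all(i %in% ok)) {
    stopf("classify_responders: unknown sustained status")
  }
  lab <- character(length(ord))
  signed <- function(s) s %in% c("up", "down")
  for (g in seq_along(ord)) {
    sl <- l[g]; si <- i[g]
    lab[g] <-
      if (sl == "not_sustained" && si == "not_sustained") {
        "none"
      } else if (signed(sl) && signed(si)) {
        if (sl == si) {
          if (sl == "up") "common_up" else "common_down"
        } else if (sl == "up") {
          "opposite_lps_up_il4_down"
        } else {
          "opposite_il4_up_lps_down"
        }
      } else if (signed(sl) && si == "inconsistent") {
        "ambiguous"
      } else if (signed(si) && sl == "inconsistent") {
        "ambiguous"
      } else if (signed(sl)) {
        if (sl == "up") "lps_specific_up" else "lps_specific_down"
      } else if (signed(si)) {
        if (si == "up") "il4_specific_up" else "il4_specific_down"
      } else {
        "ambiguous"  # inconsistent under one or both stimuli
      }
  }
  data.frame(gene_id = ord, label = lab, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Summarize responder-set sizes
#'
#' Counts the sustained, common, opposite, specific and ambiguous sets.
#' Specific counts include the opposite genes oriented in that direction
#' and satisfy the identity specific_up(stim) = sustained_up(stim) -
#' common_up - ambiguous_up(stim) (and symmetrically for down), where
#' ambiguous_up(stim) counts genes sustained up under `stim` but labeled
#' ambiguous.
#'
#' @param classes Data frame from [classify_responders()].
#' @param s_lps,s_il4 The matching sustained-status data frames.
#' @return A list of class `set_summary` with integer counts.
#' @export
summarize_sets <- function(classes, s_lps, s_il4) {
  .check_universe(classes, s_lps, "summarize_sets")
  .check_universe(classes, s_il4, "summarize_sets")
  lab <- classes$label
  l <- s_lps$status[match(classes$gene_id, s_lps$gene_id)]
  i <- s_il4$status[match(classes$gene_id, s_il4$gene_id)]
  cnt <- function(x) as.integer(sum(x))
  out <- list(
    n_genes = length(lab),
    sustained_lps_up = cnt(l == "up"),
    sustained_lps_down = cnt(l == "down"),
    sustained_il4_up = cnt(i == "up"),
    sustained_il4_down = cnt(i == "down"),
    common_up = cnt(lab == "common_up"),
    common_down = cnt(lab == "common_down"),
    opposite_lps_up_il4_down = cnt(lab == "opposite_lps_up_il4_down"),
    opposite_il4_up_lps_down = cnt(lab == "opposite_il4_up_lps_down"),
    ambiguous = cnt(lab == "ambiguous"),
    ambiguous_lps_up = cnt(lab == "ambiguous" & l == "up"),
    ambiguous_lps_down = cnt(lab == "ambiguous" & l == "down"),
    ambiguous_il4_up = cnt(lab == "ambiguous" & i == "up"),
    ambiguous_il4_down = cnt(lab == "ambiguous" & i == "down"),
    none = cnt(lab == "none")
  )
  out$opposite_total <- out$opposite_lps_up_il4_down + out$opposite_il4_up_lps_down
  # specific sets include opposite genes allocated by direction
  out$lps_specific_up <- cnt(lab == "lps_specific_up") + out$opposite_lps_up_il4_down
  out$lps_specific_down <- cnt(lab == "lps_specific_down") + out$opposite_il4_up_lps_down
  out$il4_specific_up <- cnt(lab == "il4_specific_up") + out$opposite_il4_up_lps_down
  out$il4_specific_down <- cnt(lab == "il4_specific_down") + out$opposite_lps_up_il4_down
  structure(out, class = "set_summary")
}

#' @export
print.set_summary <- function(x, ...) {
  cat("responder set summary\n")
  cat(sprintf("  sustained LPS: %d up / %d down; IL-4: %d up / %d down\n",
              x$sustained_lps_up, x$sustained_lps_down,
              x$sustained_il4_up, x$sustained_il4_down))
  cat(sprintf("  common: %d up / %d down; opposite: %d + %d = %d\n",
              x$common_up, x$common_down,
              x$opposite_lps_up_il4_down, x$opposite_il4_up_lps_down,
              x$opposite_total))
  cat(sprintf("  LPS-specific: %d up / %d down; IL-4-specific: %d up / %d down\n",
              x$lps_specific_up, x$lps_specific_down,
              x$il4_specific_up, x$il4_specific_down))
  cat(sprintf("  ambiguous: %d; none: %d\n", x$ambiguous, x$none))
  invisible(x)
}

#' Build the four enrichment input lists
#'
#' The over-representation inputs exclude common responders; opposite genes
#' are allocated to both of their directional lists (a gene up under LPS
#' and down under IL-4 contributes to `LPSup` and `IL4down`, and vice
#' versa).
#'
#' @param classes Data frame from [classify_responders()].
#' @return List of four character vectors: `LPSup`, `LPSdown`, `IL4up`,
#'   `IL4down`.
#' @export
build_go_inputs <- function(classes) {
  g <- classes$gene_id
  lab <- classes$label
  list(
    LPSup = g[lab %in% c("lps_specific_up", "opposite_lps_up_il4_down")],
    LPSdown = g[lab %in% c("lps_specific_down", "opposite_il4_up_lps_down")],
    IL4up = g[lab %in% c("il4_specific_up", "opposite_il4_up_lps_down")],
    IL4down = g[lab %in% c("il4_specific_down", "opposite_lps_up_il4_down")]
  )
}

#' Venn-style per-direction tally for one stimulus
#'
#' Reproduces the diagram accounting in which a direction-flipping gene
#' (significant at both timepoints with opposite signs) is counted in both
#' the up and the down tally, alongside the sustained genes of each
#' direction. This is a reporting view, not part of the responder
#' partition.
#'
#' @param calls_12,calls_24 DEG-call data frames for one stimulus.
#' @return Named integer vector `c(up = ..., down = ...)`.
#' @export
direction_tally <- function(calls_12, calls_24) {
  .check_universe(calls_12, calls_24, "direction_tally")
  d12 <- calls_12$direction
  d24 <- calls_24$direction[match(calls_12$gene_id, calls_24$gene_id)]
  both <- d12 != "ns" & d24 != "ns"
  c(up = as.integer(sum(both & (d12 == "up" | d24 == "up"))),
    down = as.integer(sum(both & (d12 == "down" | d24 == "down"))))
}
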