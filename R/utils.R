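# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package code does
#' not perturb the caller's random number stream.
#'
#' @param seed Integer seed passed to [set.seed()].
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

# Allowed vocabularies for the experimental design.
.stimuli <- c("control", "LPS", "IL4")
.treatments <- c("LPS", "IL4")
.timepoints <- c(12L, 24L)

# Condition label in the field's shorthand, e.g. "12LPS", "24C".
condition_label <- function(stimulus, timepoint) {
  short <- ifelse(stimulus == "control", "C", stimulus)
  paste0(timepoint, short)
}

contrast_label <- function(stimulus, timepoint) {
  sprintf("%s_%dh", stimulus, timepoint)
}
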