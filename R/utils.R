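`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a child seed for a named pipeline stage
#'
#' A single user-facing seed is fanned out to per-stage seeds by hashing the
#' stage name, so inserting or reordering stages does not perturb the random
#' stream of the others.  The hash is a small deterministic polynomial over
#' the stage name's character codes; results stay below 2^31.
#'
#' @param seed integer master seed.
#' @param stage character scalar naming the stage.
#' @return an integer seed in `[0, 2^31)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 1000003
  as.integer(((as.numeric(seed) %% 1000003) * 1009 + h) %% 2147483647)
}

timepoint_levels <- function() c("Ctrl", "T1", "T2", "T3", "T4")

# order a vector of time point labels canonically
order_timepoints <- function(x) factor(x, levels = timepoint_levels())
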