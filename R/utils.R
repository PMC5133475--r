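## Internal helpers shared across modules.

#' @importFrom stats rnorm runif rbinom rpois qnorm pnorm pchisq pgamma
#'   qchisq lm optimize sd median complete.cases ks.test p.adjust setNames
NULL

# Sample keys combine family and individual ids; "/" keeps them reversible
# as long as ids themselves avoid it (enforced nowhere -- ids are opaque).
makeSampleKeys <- function(family_id, individual_id) {
  paste(family_id, individual_id, sep = "/")
}

# Deterministic stream of sub-seeds from a master seed, so that each
# stochastic stage of a pipeline run has its own reproducible seed and
# stages stay invariant to one another's draw counts.
streamSeeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / s
}

# One timestamped log line per pipeline stage.
stageLog <- function(..., verbose = TRUE) {
  if (verbose)
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
  invisible(NULL)
}
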