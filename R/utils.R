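#' @importFrom rlang abort warn inform %||%
#' @importFrom stats predict quantile sd rnorm runif kmeans dnorm dist
#' @importFrom utils head
NULL

# Deterministic child-seed derivation: every stochastic step consumes a seed
# derived from the master seed by a fixed offset, so reordering independent
# steps never perturbs the others. Kept inside 32-bit signed range.
child_seed <- function(master, offset) {
  master <- as.double(master %% 2147483647L)
  as.integer((master * 7919 + as.double(offset) * 104729 + 1) %% 2147483647)
}

# Run `expr` under a temporary RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- rlang::`%||%`

# size-safe sampling (sample() treats a scalar as 1:n)
sample_from <- function(v, k) v[sample.int(length(v), k)]

# progress logging to stderr, off by default (CLI turns it on)
log_info <- function(fmt, ...) {
  if (isTRUE(getOption("metl.verbose", FALSE)))
    message(sprintf(fmt, ...))
  invisible(NULL)
}
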