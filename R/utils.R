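# Internal helpers shared across modules.

#' Derive a named substream seed from a root seed
#'
#' All stochastic stages (haplotypes, panels, missingness, traits, ...) draw
#' their own seed from the run's root seed plus a stream name, so that each
#' stage is independently reproducible and insensitive to the order in which
#' other stages consume random numbers.
#'
#' @param seed integer root seed.
#' @param stream character stream name, e.g. `"haplotypes"`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483563
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% m
  as.integer(((abs(seed) %% m) * 48271 + h) %% m) + 1L
}

# evaluate `expr` under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# order of (chrom, pos) pairs, chromosomes in first-appearance order
genome_order <- function(chrom, pos) {
  order(match(chrom, unique(chrom)), pos)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
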