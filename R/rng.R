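## Seed plumbing. All stochastic entry points take an integer `seed` and use
## L'Ecuyer-CMRG streams (parallel::nextRNGStream) internally, so that
## (i) results are reproducible bit-for-bit under a given seed, and
## (ii) per-lineage substreams are stable: enlarging a synthetic dataset
## never perturbs the lineages already generated.

## Evaluate `expr` with the RNG state set from `seed` (L'Ecuyer-CMRG),
## restoring the caller's RNG state afterwards.
with_master_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG")
  expr
}

## The i-th independent stream spawned from `seed` (i = 1, 2, ...).
rng_stream <- function(seed, i = 1L) {
  with_master_seed(seed, {
    s <- get(".Random.seed", envir = globalenv())
    for (k in seq_len(i)) s <- parallel::nextRNGStream(s)
    s
  })
}

## Run `expr` under stream i of `seed`.
with_stream <- function(seed, i, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  assign(".Random.seed", rng_stream(seed, i), envir = globalenv())
  expr
}

## Advance to the substream for unit `j` within an existing stream state.
next_substream <- function(state) parallel::nextRNGSubStream(state)

#' Derive a stage seed from a master seed
#'
#' Deterministic scheme used by [run_pipeline()] to give every pipeline
#' stage its own seed: a small polynomial hash of the stage label folded
#' into the master seed, always below 2^31. Identical master seed and
#' stage label always yield the same stage seed.
#'
#' @param seed integer master seed.
#' @param stage character stage label.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- utils::head(utf8ToInt(paste0(stage, ":")), 32L)
  acc <- as.double(seed) %% 2147483647
  for (v in h) acc <- (acc * 31 + v) %% 2147483647
  as.integer(acc)
}
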