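#' Synthetic occupancy dataset from a known binomial mixture
#'
#' Generates lineages by the same two-step process the Bayesian model
#' assumes: lineage i is assigned a type drawn categorically with
#' frequencies `f`, then each layer count is drawn Binomial(`n_max`,
#' `p[type, layer]`). Ground-truth type labels are returned for
#' parameter-recovery checks. A master seed spawns one RNG substream per
#' lineage, so enlarging `n` never perturbs the lineages already
#' generated.
#'
#' @param k number of types.
#' @param p k x 4 matrix of occupancy probabilities, columns in
#'   generation order `l6, l5, l4, l23` (unnamed columns are taken in
#'   that order).
#' @param f length-k mixture fractions summing to 1.
#' @param n number of lineages.
#' @param n_max binomial cap (default 20).
#' @param seed integer seed.
#' @return list with `S` (n x 4 occupancy matrix, generation order),
#'   `truth` (data frame `lineage_id`, `true_type`), and `table` (the
#'   corresponding [lineage_table()], `method = "simulated"`).
#' @export
generate_occupancy_dataset <- function(k, p, f, n, n_max = 20L, seed = 1L) {
  p <- rbind(p)
  stopifnot(nrow(p) == k, ncol(p) == 4L, all(p >= 0), all(p <= 1),
            length(f) == k, n >= 1L)
  if (abs(sum(f) - 1) > 1e-8) stop("mixture fractions must sum to 1",
                                   call. = FALSE)
  colnames(p) <- .gen_layers
  S <- matrix(0L, n, 4L, dimnames = list(NULL, .gen_layers))
  true_type <- integer(n)
  state <- rng_stream(seed, 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  for (i in seq_len(n)) {
    state <- next_substream(state)
    assign(".Random.seed", state, envir = globalenv())
    ti <- if (k == 1L) 1L else sample.int(k, 1L, prob = f)
    true_type[i] <- ti
    S[i, ] <- stats::rbinom(4L, n_max, p[ti, ])
  }
  ids <- sprintf("occ%05d", seq_len(n))
  rownames(S) <- ids
  tab <- data.frame(lineage_id = ids, method = "simulated",
                    area = "synthetic", age = "synthetic",
                    stringsAsFactors = FALSE)
  tab[.disp_layers] <- S[, .disp_layers]
  list(S = S, truth = data.frame(lineage_id = ids, true_type = true_type,
                                 stringsAsFactors = FALSE),
       table = lineage_table(tab))
}

#' Synthetic lineage dataset from the sequential simulator
#'
#' Labelled wrapper around [simulate_model()]: generates one replicate of
#' `spec$n_progenitors` lineages with the sequential generator, recording
#' each progenitor's true type *before* any size filtering (the filter is
#' applied downstream so that it can itself be tested).
#'
#' @param spec a [sim_model_spec()] (its `size_filter` and `n_repeats`
#'   are ignored here: one unfiltered replicate is produced).
#' @param seed integer seed (overrides `spec$seed`).
#' @return list with `table` (unfiltered [lineage_table()]) and `truth`
#'   (data frame `lineage_id`, `true_type`, `interrupted`).
#' @export
generate_lineage_dataset <- function(spec, seed = spec$seed) {
  spec$seed <- as.integer(seed)
  spec$n_repeats <- 1L
  spec$size_filter <- NULL
  rep1 <- simulate_model(spec, keep_truth = TRUE)[[1L]]
  tr <- attr(rep1, "truth")
  attr(rep1, "truth") <- NULL
  list(table = rep1,
       truth = data.frame(lineage_id = rep1$lineage_id,
                          true_type = tr$true_type,
                          interrupted = tr$interrupted,
                          stringsAsFactors = FALSE))
}

#' Two-population simulator preset
#'
#' An experiment-like default specification with two progenitor
#' populations: a majority type producing larger translaminar clones
#' (centred near eight cells) and a minority type producing small,
#' superficially biased clones (centred near four cells). Together they
#' yield a bimodal clonal-size distribution and a negative
#' superficial-deep correlation. The parameter values are this package's
#' own choices for a realistic synthetic benchmark.
#'
#' @param n_progenitors,n_repeats,seed passed to [sim_model_spec()].
#' @return a [sim_model_spec()] with two types.
#' @export
synthetic_preset <- function(n_progenitors = 100L, n_repeats = 100L,
                             seed = 1L) {
  major <- progenitor_spec(
    M = c(l6 = 4L, l5 = 4L, l4 = 2L, l23 = 5L),
    P = c(l6 = 1.0, l5 = 1.0, l4 = 0.65, l23 = 0.70),
    q = 0.02, fraction = 0.62)
  minor <- progenitor_spec(
    M = c(l6 = 1L, l5 = 1L, l4 = 2L, l23 = 3L),
    P = c(l6 = 0.03, l5 = 0.03, l4 = 0.85, l23 = 0.95),
    q = 0.02, fraction = 0.38)
  sim_model_spec(list(major, minor), n_progenitors = n_progenitors,
                 n_repeats = n_repeats, seed = seed)
}
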