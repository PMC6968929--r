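#' Permute neurons among lineages, conserving laminar identities
#'
#' Pools every neuron of the dataset as a layer label, shuffles the pool
#' uniformly at random, and refills lineages of the original sizes in the
#' original order. By construction each lineage keeps its total cell
#' number and each layer keeps its grand total; only the assignment of
#' neurons to lineages is randomised. This is the null model for asking
#' whether lineage structure carries information beyond layer-wise neuron
#' densities and the clone-size distribution.
#'
#' @param x non-empty lineage table.
#' @return a lineage table of the same shape with permuted layer counts
#'   (method and metadata columns preserved).
#' @export
permute_dataset <- function(x) {
  if (nrow(x) == 0L) stop("cannot permute an empty dataset", call. = FALSE)
  counts <- as.matrix(x[, .disp_layers, drop = FALSE])
  sizes <- rowSums(counts)
  ## one layer index per neuron, shuffled
  pool <- rep(rep(seq_len(4L), nrow(x)), as.vector(t(counts)))
  pool <- sample(pool)
  lineage_of <- rep(seq_len(nrow(x)), sizes)
  new_counts <- matrix(0L, nrow(x), 4L,
                       dimnames = list(NULL, .disp_layers))
  if (length(pool) > 0L) {
    tab <- table(factor(lineage_of, levels = seq_len(nrow(x))),
                 factor(pool, levels = 1:4))
    new_counts[] <- as.integer(tab)
  }
  out <- x
  out[, .disp_layers] <- new_counts
  out
}

#' Permutation analysis of lineage structure
#'
#' Repeats [permute_dataset()] `n_repeats` times (default 1000) and, for
#' each permuted dataset, records the summary statistics of
#' [summarize_lineages()]. The report contrasts the observed statistics
#' with the permutation mean and standard deviation, and flags observed
#' statistics falling outside mean +/- `flag_sd` standard deviations.
#' Statistics conserved by construction (per-layer totals, size histogram)
#' are asserted identical on every repeat.
#'
#' @param x non-empty lineage table (apply [neurogenic_filter()] upstream
#'   if the analysis calls for it).
#' @param n_repeats number of permutations (>= 1).
#' @param seed integer seed.
#' @param flag_sd flag threshold in permutation standard deviations.
#' @return list of class `permutation_report` with elements `n_repeats`,
#'   `observed` (named vector of statistics), `perm_mean`, `perm_sd`
#'   (NA when `n_repeats == 1`), `flagged` (logical), and `perm_values`
#'   (matrix of per-repeat statistics).
#' @export
run_permutation_analysis <- function(x, n_repeats = 1000L, seed = 1L,
                                     flag_sd = 2) {
  if (n_repeats < 1L) stop("n_repeats must be >= 1", call. = FALSE)
  if (nrow(x) == 0L) stop("empty dataset", call. = FALSE)
  obs <- .perm_stat_vector(x)
  layer_tot <- colSums(as.matrix(x[, .disp_layers, drop = FALSE]))
  size_ms <- sort(lineage_sizes(x))
  perm <- with_master_seed(seed, {
    vapply(seq_len(n_repeats), function(i) {
      px <- permute_dataset(x)
      ## conservation asserted on every repeat
      stopifnot(identical(colSums(as.matrix(px[, .disp_layers])), layer_tot),
                identical(sort(lineage_sizes(px)), size_ms))
      .perm_stat_vector(px)
    }, numeric(length(obs)))
  })
  perm <- t(perm)
  colnames(perm) <- names(obs)
  m <- colMeans(perm)
  s <- if (n_repeats >= 2L) apply(perm, 2L, stats::sd) else
    rep(NA_real_, length(obs))
  flagged <- !is.na(s) & s > 0 & abs(obs - m) > flag_sd * s
  out <- list(n_repeats = n_repeats, observed = obs, perm_mean = m,
              perm_sd = s, flagged = flagged, perm_values = perm,
              flag_sd = flag_sd)
  class(out) <- c("permutation_report", "list")
  out
}

## Flat named statistic vector for one dataset: laminar fractions, class
## fractions, configuration frequencies, Spearman r (NA when undefined).
.perm_stat_vector <- function(x) {
  lf <- laminar_fractions(x)
  cf <- class_fractions(x)
  qf <- config_frequencies(x)
  r <- tryCatch(superficial_deep_correlation(x), error = function(e) NA_real_)
  c(stats::setNames(lf, paste0("frac_", names(lf))),
    stats::setNames(as.numeric(cf), paste0("class_", names(cf))),
    stats::setNames(as.numeric(qf), paste0("config_", names(qf))),
    spearman_r = r)
}

#' @export
print.permutation_report <- function(x, ...) {
  cat("Permutation analysis: ", x$n_repeats, " repeats\n", sep = "")
  keep <- c(grep("^frac_|^class_", names(x$observed), value = TRUE),
            "spearman_r")
  df <- data.frame(observed = round(x$observed[keep], 4),
                   perm_mean = round(x$perm_mean[keep], 4),
                   perm_sd = round(x$perm_sd[keep], 4),
                   flagged = x$flagged[keep])
  print(df)
  nf <- sum(x$flagged, na.rm = TRUE)
  cat(nf, " statistic(s) outside mean +/- ", x$flag_sd, " sd\n", sep = "")
  invisible(x)
}
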