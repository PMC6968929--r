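#' Laminar fractions of a dataset
#'
#' Fraction of all neurons in each cortical layer (II/III, IV, V, VI),
#' pooled over lineages. Sums to 1.
#'
#' @param x lineage table with at least one neuron in total.
#' @return named numeric vector `c(l23, l4, l5, l6)`.
#' @export
laminar_fractions <- function(x) {
  if (nrow(x) == 0L) stop("empty dataset", call. = FALSE)
  tot <- colSums(as.matrix(x[, .disp_layers, drop = FALSE]))
  if (sum(tot) == 0) stop("dataset contains no neurons", call. = FALSE)
  tot / sum(tot)
}

#' Clonal size histogram
#'
#' Counts of lineages by total cell number over an inclusive size range
#' (default the 3-12 neurogenic window). Out-of-range lineages are tallied
#' in the `n_below`/`n_above` attributes rather than dropped silently.
#'
#' @param x lineage table.
#' @param range length-2 integer vector, inclusive size range.
#' @return named integer vector of counts per size, with attributes
#'   `n_below` and `n_above`.
#' @export
size_histogram <- function(x, range = c(3L, 12L)) {
  stopifnot(length(range) == 2L, range[1L] <= range[2L])
  n <- lineage_sizes(x)
  sizes <- seq.int(range[1L], range[2L])
  h <- vapply(sizes, function(s) sum(n == s), integer(1L))
  names(h) <- as.character(sizes)
  attr(h, "n_below") <- sum(n < range[1L])
  attr(h, "n_above") <- sum(n > range[2L])
  h
}

#' Fractions of translaminar and laminar-restricted lineages
#'
#' Applies [classify_laminar()] per lineage and returns the fractions of
#' the three classes (summing to 1).
#'
#' @param x non-empty lineage table of non-empty lineages.
#' @return named numeric vector `c(translaminar, deep_restricted,
#'   superficial_restricted)`.
#' @export
class_fractions <- function(x) {
  if (nrow(x) == 0L) stop("empty dataset", call. = FALSE)
  cl <- classify_laminar(x)
  c(table(cl)) / length(cl)
}

#' Laminar configuration frequencies
#'
#' Relative frequency of each of the 15 non-empty laminar configurations
#' (see [configuration_code()]); sums to 1.
#'
#' @param x non-empty lineage table of non-empty lineages.
#' @return named numeric vector of length 15.
#' @export
config_frequencies <- function(x) {
  if (nrow(x) == 0L) stop("empty dataset", call. = FALSE)
  cc <- configuration_code(x)
  c(table(cc)) / length(cc)
}

#' Superficial-deep correlation across lineages
#'
#' Spearman rank correlation (average ranks for ties) between the number of
#' neurons each clone places in superficial (II/III + IV) versus deep
#' (V + VI) layers. With `fractions = TRUE` the per-clone superficial and
#' deep fractions of clone size are correlated instead of raw counts.
#'
#' @param x lineage table with at least 3 rows.
#' @param fractions correlate per-clone fractions instead of counts.
#' @return Spearman's r.
#' @export
superficial_deep_correlation <- function(x, fractions = FALSE) {
  if (nrow(x) < 3L) stop("need at least 3 lineages", call. = FALSE)
  s <- as.numeric(superficial_counts(x))
  d <- as.numeric(deep_counts(x))
  if (fractions) {
    tot <- s + d
    if (any(tot == 0)) stop("empty lineage(s); cannot take fractions",
                            call. = FALSE)
    s <- s / tot
    d <- d / tot
  }
  if (stats::var(s) == 0 || stats::var(d) == 0) {
    stop("superficial or deep counts are constant; correlation undefined",
         call. = FALSE)
  }
  stats::cor(s, d, method = "spearman")
}

#' Subtype diversity of all-layer translaminar lineages
#'
#' Among translaminar lineages occupying every layer (configuration
#' `"1111"`) with complete projection-subtype annotation, the fraction
#' containing exactly 1, 2, 3 or 4 of the CCPN/SCPN/CThPN/HPN subclasses.
#' Lineages whose subtype counts do not account for every cell contain
#' unclassified cells and are excluded (their number is reported in the
#' `n_excluded` attribute).
#'
#' @param x lineage table with columns `n_ccpn`, `n_scpn`, `n_cthpn`,
#'   `n_hpn`.
#' @return numeric vector of length 4 (`"1"` to `"4"` subclasses), summing
#'   to 1 over the included lineages, with attributes `n_included` and
#'   `n_excluded`.
#' @export
subtype_diversity <- function(x) {
  sub_cols <- c("n_ccpn", "n_scpn", "n_cthpn", "n_hpn")
  if (!all(sub_cols %in% names(x))) {
    stop("subtype counts (n_ccpn, n_scpn, n_cthpn, n_hpn) required",
         call. = FALSE)
  }
  full <- !is.na(configuration_code(x)) & configuration_code(x) == "1111"
  x <- x[full, , drop = FALSE]
  sub <- as.matrix(x[, sub_cols, drop = FALSE])
  complete <- !apply(sub, 1L, anyNA) & rowSums(sub) == lineage_sizes(x)
  n_excluded <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  sub <- sub[complete, , drop = FALSE]
  if (nrow(x) == 0L) stop("no fully annotated all-layer lineages",
                          call. = FALSE)
  k <- rowSums(sub > 0L)
  out <- vapply(1:4, function(i) mean(k == i), numeric(1L))
  names(out) <- as.character(1:4)
  attr(out, "n_included") <- nrow(x)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Model-data z-score
#'
#' Distance between an experimental value and the distribution of the same
#' statistic across simulation repeats: the absolute difference between the
#' experimental value and the mean over repeats, divided by the (sample,
#' n-1 denominator) standard deviation over repeats. Values above 1 flag a
#' model-data distance larger than the repeat-to-repeat variability.
#'
#' @param experimental observed scalar statistic.
#' @param sim_values the same statistic across >= 2 simulation repeats.
#' @return non-negative z value.
#' @export
zscore <- function(experimental, sim_values) {
  stopifnot(is.numeric(experimental), length(experimental) == 1L,
            is.numeric(sim_values))
  if (length(sim_values) < 2L) stop("need >= 2 simulation values",
                                    call. = FALSE)
  s <- stats::sd(sim_values)
  if (s == 0) stop("simulation spread is zero; z-score undefined",
                   call. = FALSE)
  abs(mean(sim_values) - experimental) / s
}

#' Categorical and size comparisons between datasets
#'
#' For comparisons of distributions over fractions of a total
#' (`type = "counts"`: two aligned count vectors, or an observed count
#' vector against expected fractions) a chi-square test is used, replaced
#' by Fisher's exact test when the table is 2x2 or any expected cell count
#' falls below 5. For clone-size comparisons (`type = "sizes"`) a
#' Mann-Whitney rank-sum test is used.
#'
#' @param a,b for `"counts"`: non-negative count vectors over the same
#'   categories (`b` may instead be a fraction vector summing to 1, tested
#'   against `a` with a goodness-of-fit chi-square); for `"sizes"`: two
#'   numeric samples of clone sizes.
#' @param type `"counts"` or `"sizes"`.
#' @return list with `test` (name of the test applied), `statistic`,
#'   `p.value`.
#' @export
compare_datasets <- function(a, b, type = c("counts", "sizes")) {
  type <- match.arg(type)
  if (type == "sizes") {
    ht <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
    return(list(test = "mann-whitney", statistic = unname(ht$statistic),
                p.value = ht$p.value))
  }
  stopifnot(is.numeric(a), is.numeric(b), all(a >= 0), all(b >= 0))
  if (sum(a) == 0 || sum(b) == 0) stop("zero-total input", call. = FALSE)
  if (abs(sum(b) - 1) < 1e-8 && any(b != floor(b))) {
    ## goodness-of-fit against expected fractions
    ht <- stats::chisq.test(a, p = b)
    return(list(test = "chi-square-gof", statistic = unname(ht$statistic),
                p.value = ht$p.value))
  }
  if (length(a) != length(b)) stop("category sets differ", call. = FALSE)
  tab <- rbind(a, b)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_fisher <- all(dim(tab) == c(2L, 2L)) || any(expected < 5)
  if (use_fisher) {
    ht <- stats::fisher.test(tab, workspace = 2e6)
    list(test = "fisher", statistic = NA_real_, p.value = ht$p.value)
  } else {
    ht <- stats::chisq.test(tab)
    list(test = "chi-square", statistic = unname(ht$statistic),
         p.value = ht$p.value)
  }
}

#' Summary statistics bundle
#'
#' Computes the full set of summaries used for model-data comparison:
#' laminar fractions, clonal size histogram, class fractions, configuration
#' frequencies and the superficial-deep Spearman correlation.
#'
#' @param x lineage table.
#' @param size_range inclusive clone-size range for the histogram.
#' @param correlation compute the Spearman correlation (requires >= 3
#'   lineages and non-constant compartment counts; set `FALSE` to skip).
#' @return list of class `pc_summary`.
#' @export
summarize_lineages <- function(x, size_range = c(3L, 12L),
                               correlation = TRUE) {
  if (nrow(x) == 0L) stop("empty dataset", call. = FALSE)
  r <- try(if (correlation) superficial_deep_correlation(x) else NA_real_,
           silent = TRUE)
  if (inherits(r, "try-error")) r <- NA_real_
  out <- list(
    n_lineages = nrow(x),
    laminar_fractions = laminar_fractions(x),
    size_histogram = size_histogram(x, size_range),
    class_fractions = class_fractions(x),
    config_frequencies = config_frequencies(x),
    spearman_r = r)
  class(out) <- c("pc_summary", "list")
  out
}

#' @export
print.pc_summary <- function(x, ...) {
  cat("Lineage summary (", x$n_lineages, " lineages)\n", sep = "")
  lf <- round(100 * x$laminar_fractions, 1)
  cat("  cells per layer (%): II/III ", lf[["l23"]], ", IV ", lf[["l4"]],
      ", V ", lf[["l5"]], ", VI ", lf[["l6"]], "\n", sep = "")
  cf <- round(100 * as.numeric(x$class_fractions), 1)
  cat("  classes (%): translaminar ", cf[1L], ", deep-restricted ", cf[2L],
      ", superficial-restricted ", cf[3L], "\n", sep = "")
  cat("  superficial-deep Spearman r: ",
      if (is.na(x$spearman_r)) "NA" else round(x$spearman_r, 3), "\n",
      sep = "")
  invisible(x)
}
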