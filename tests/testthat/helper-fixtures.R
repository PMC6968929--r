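## Small in-code fixtures shared across test files.

## Build a lineage table from a matrix/data.frame of layer counts
## (columns l23, l4, l5, l6 in that order when unnamed).
make_lineages <- function(counts, method = "genetic", area = "S1",
                          age = "P21", ...) {
  counts <- rbind(counts)
  if (is.null(colnames(counts)) ||
      !all(colnames(counts) %in% c("l23", "l4", "l5", "l6"))) {
    colnames(counts) <- c("l23", "l4", "l5", "l6")
  }
  df <- data.frame(lineage_id = sprintf("L%03d", seq_len(nrow(counts))),
                   method = method, area = area, age = age,
                   stringsAsFactors = FALSE)
  df[colnames(counts)] <- as.data.frame(counts)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  lineage_table(df)
}

## A small mixed dataset: translaminar, deep- and superficial-restricted.
mixed_fixture <- function() {
  make_lineages(rbind(
    c(2, 1, 2, 3),   # translaminar, 8 cells
    c(0, 0, 2, 3),   # deep-restricted, 5 cells
    c(3, 2, 0, 0),   # superficial-restricted, 5 cells
    c(1, 1, 1, 1),   # translaminar, all layers
    c(2, 0, 1, 1)))  # translaminar, no layer IV
}

## Exact marginal likelihood of a set of occupancy rows sharing one type:
## integrates the (coefficient-free) binomial likelihood over the Beta
## prior, layer by layer. Rows and mask in generation order.
marginal_loglik_one_type <- function(S, sigma, n_max, a, b) {
  S <- rbind(S); sigma <- rbind(sigma)
  sum(vapply(seq_len(ncol(S)), function(j) {
    ssum <- sum(sigma[, j] * S[, j])
    fsum <- sum(sigma[, j] * (n_max - S[, j]))
    lbeta(a + ssum, b + fsum) - lbeta(a, b)
  }, numeric(1L)))
}
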