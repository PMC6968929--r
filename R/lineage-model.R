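#' Construct or validate a lineage table
#'
#' A lineage table is a data frame with one row per clone. Required columns:
#' `lineage_id` (unique identifier), `method` (one of `"retroviral"`,
#' `"madm"`, `"genetic"`, `"simulated"`), `area` (cortical area label, e.g.
#' `"S1"`), `age` (e.g. `"P21"`), and the per-layer neuron counts `l23`,
#' `l4`, `l5`, `l6` (non-negative integers). Optional columns: MADM subclone
#' counts `a_l23 ... a_l6` and `b_l23 ... b_l6` (when both sets are present
#' their per-layer sums must equal the main counts), and projection-subtype
#' counts `n_ccpn`, `n_scpn`, `n_cthpn`, `n_hpn` (their sum must not exceed
#' the clone size).
#'
#' @param x data frame with at least the required columns.
#' @return `x` with class `lineage_table` prepended, after validation.
#' @examples
#' lt <- lineage_table(data.frame(
#'   lineage_id = c("L1", "L2"), method = "genetic", area = "S1", age = "P21",
#'   l23 = c(2L, 0L), l4 = c(1L, 0L), l5 = c(0L, 2L), l6 = c(1L, 3L)))
#' classify_laminar(lt)
#' @export
lineage_table <- function(x) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("lineage_id", "method", "area", "age", .disp_layers)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) {
    stop("lineage table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_method <- setdiff(unique(as.character(x$method)),
                        c("retroviral", "madm", "genetic", "simulated"))
  if (length(bad_method) > 0L) {
    stop("unknown method value(s): ", paste(bad_method, collapse = ", "),
         call. = FALSE)
  }
  count_cols <- intersect(
    c(.disp_layers,
      paste0("a_", .disp_layers), paste0("b_", .disp_layers),
      c("n_ccpn", "n_scpn", "n_cthpn", "n_hpn")),
    names(x))
  for (cc in count_cols) {
    v <- x[[cc]]
    if (anyNA(v)) {
      stop("column '", cc, "' contains missing values (row ",
           paste(which(is.na(v)), collapse = ", "),
           "); blank cells are not interpreted as zero", call. = FALSE)
    }
    if (!is.numeric(v) || any(v < 0) || any(v != floor(v))) {
      bad <- which(!is.finite(v) | v < 0 | v != floor(v))
      stop("column '", cc, "' must hold non-negative integers (row ",
           paste(bad, collapse = ", "), ")", call. = FALSE)
    }
    x[[cc]] <- as.integer(v)
  }
  a_cols <- paste0("a_", .disp_layers)
  b_cols <- paste0("b_", .disp_layers)
  if (all(a_cols %in% names(x)) && all(b_cols %in% names(x))) {
    has_sub <- stats::complete.cases(x[, c(a_cols, b_cols)])
    for (j in .disp_layers) {
      tot <- x[[paste0("a_", j)]] + x[[paste0("b_", j)]]
      bad <- which(has_sub & tot != x[[j]])
      if (length(bad) > 0L) {
        stop("subclone counts do not sum to clone counts in layer ", j,
             " (row ", paste(bad, collapse = ", "), ")", call. = FALSE)
      }
    }
  }
  sub_cols <- c("n_ccpn", "n_scpn", "n_cthpn", "n_hpn")
  if (any(sub_cols %in% names(x))) {
    present <- intersect(sub_cols, names(x))
    st <- rowSums(as.matrix(x[, present, drop = FALSE]))
    bad <- which(st > lineage_sizes(x))
    if (length(bad) > 0L) {
      stop("subtype counts exceed clone size (row ",
           paste(bad, collapse = ", "), ")", call. = FALSE)
    }
  }
  class(x) <- unique(c("lineage_table", class(x)))
  x
}

#' Per-lineage cell counts and compartment sums
#'
#' `lineage_sizes()` returns the total number of neurons per clone,
#' `superficial_counts()` the number in layers II/III and IV, and
#' `deep_counts()` the number in layers V and VI.
#'
#' @param x data frame with layer-count columns `l23`, `l4`, `l5`, `l6`.
#' @return integer vector, one value per row of `x`.
#' @export
lineage_sizes <- function(x) {
  as.integer(rowSums(as.matrix(x[, .disp_layers, drop = FALSE])))
}

#' @rdname lineage_sizes
#' @export
superficial_counts <- function(x) {
  as.integer(rowSums(as.matrix(x[, .sup_layers, drop = FALSE])))
}

#' @rdname lineage_sizes
#' @export
deep_counts <- function(x) {
  as.integer(rowSums(as.matrix(x[, .deep_layers, drop = FALSE])))
}

#' Classify lineages by laminar compartment
#'
#' A clone is *translaminar* when it contains neurons in both the deep
#' (V and VI) and superficial (II/III and IV) compartments,
#' *deep-restricted* when all neurons sit in layers V-VI, and
#' *superficial-restricted* when all sit in layers II/III-IV.
#'
#' @param x lineage table (or any data frame with the four layer columns).
#' @return factor with levels `translaminar`, `deep_restricted`,
#'   `superficial_restricted`, one value per row.
#' @seealso [class_fractions()]
#' @export
classify_laminar <- function(x) {
  s <- superficial_counts(x)
  d <- deep_counts(x)
  if (any(s + d == 0L)) {
    stop("cannot classify empty lineage(s) (row ",
         paste(which(s + d == 0L), collapse = ", "), ")", call. = FALSE)
  }
  out <- ifelse(s >= 1L & d >= 1L, "translaminar",
                ifelse(d >= 1L, "deep_restricted", "superficial_restricted"))
  factor(out, levels = c("translaminar", "deep_restricted",
                         "superficial_restricted"))
}

#' Laminar configuration codes
#'
#' The configuration of a clone is its presence/absence pattern across the
#' four layers, written as a 4-character string of 0/1 in the order
#' II/III, IV, V, VI (e.g. `"1011"` = occupied in II/III, V and VI but not
#' IV). There are 15 possible non-empty configurations, enumerated by
#' `config_levels()`.
#'
#' @param x lineage table (or data frame with the four layer columns).
#' @return factor over the 15 configuration codes, one value per row.
#' @export
configuration_code <- function(x) {
  m <- as.matrix(x[, .disp_layers, drop = FALSE]) > 0L
  if (any(rowSums(m) == 0L)) {
    stop("cannot derive a configuration for empty lineage(s) (row ",
         paste(which(rowSums(m) == 0L), collapse = ", "), ")", call. = FALSE)
  }
  codes <- apply(m, 1L, function(r) paste(as.integer(r), collapse = ""))
  factor(codes, levels = config_levels())
}

#' @rdname configuration_code
#' @export
config_levels <- function() {
  g <- expand.grid(l6 = 0:1, l5 = 0:1, l4 = 0:1, l23 = 0:1)
  g <- g[rowSums(g) > 0L, c("l23", "l4", "l5", "l6")]
  codes <- apply(g, 1L, paste, collapse = "")
  sort(unname(codes), decreasing = TRUE)
}

#' Filter lineages to the neurogenic size range
#'
#' Clones smaller than `min_size` cells are excluded (one- and two-cell
#' clones arise from labelling of a neuron or an intermediate progenitor
#' rather than an apical progenitor), and clones larger than `max_size`
#' cells are excluded as likely products of symmetric proliferative
#' divisions. Defaults follow the standard 3-12 cell neurogenic window.
#'
#' @param x lineage table.
#' @param min_size,max_size inclusive bounds on clone size.
#' @return the filtered lineage table, original row order preserved.
#' @export
neurogenic_filter <- function(x, min_size = 3L, max_size = 12L) {
  stopifnot(min_size <= max_size)
  n <- lineage_sizes(x)
  x[n >= min_size & n <= max_size, , drop = FALSE]
}

#' Split MADM lineages into reporter subclones
#'
#' In MADM (mosaic analysis with double markers) experiments a G2-X
#' recombination labels the two daughter sub-lineages of a dividing
#' progenitor with different reporters. Lineages with three or more cells in
#' *each* reporter derive from symmetric proliferative divisions and are
#' labelled `symmetric`; lineages with one or two cells in total are
#' labelled `excluded_small`; the remainder are `asymmetric_neurogenic` and
#' are the informative clones for neurogenic analyses.
#'
#' @param x lineage table with `method == "madm"` and complete subclone
#'   columns `a_l23 ... a_l6`, `b_l23 ... b_l6`.
#' @return list with elements `division` (factor per row: `symmetric`,
#'   `asymmetric_neurogenic`, `excluded_small`) and `subclones` (a lineage
#'   table with two rows per input clone, one per reporter, carrying the
#'   per-reporter layer counts; columns `parent_id` and `reporter` identify
#'   the origin).
#' @export
split_madm_lineage <- function(x) {
  a_cols <- paste0("a_", .disp_layers)
  b_cols <- paste0("b_", .disp_layers)
  if (!all(c(a_cols, b_cols) %in% names(x))) {
    stop("MADM split requires subclone columns a_l23..a_l6 and b_l23..b_l6",
         call. = FALSE)
  }
  if (anyNA(x[, c(a_cols, b_cols)])) {
    stop("missing subclone counts; cannot split", call. = FALSE)
  }
  if (!all(x$method == "madm")) {
    stop("split_madm_lineage() applies to method == 'madm' lineages",
         call. = FALSE)
  }
  a_tot <- as.integer(rowSums(as.matrix(x[, a_cols])))
  b_tot <- as.integer(rowSums(as.matrix(x[, b_cols])))
  division <- ifelse(a_tot >= 3L & b_tot >= 3L, "symmetric",
                     ifelse(a_tot + b_tot <= 2L, "excluded_small",
                            "asymmetric_neurogenic"))
  division <- factor(division, levels = c("symmetric",
                                          "asymmetric_neurogenic",
                                          "excluded_small"))
  sub <- function(cols, rep_label) {
    d <- data.frame(
      lineage_id = paste0(x$lineage_id, ".", rep_label),
      parent_id = x$lineage_id,
      reporter = rep_label,
      method = "madm", area = x$area, age = x$age,
      stringsAsFactors = FALSE)
    d[.disp_layers] <- x[, cols]
    d
  }
  subclones <- rbind(sub(a_cols, "a"), sub(b_cols, "b"))
  subclones <- subclones[order(subclones$parent_id, subclones$reporter), ]
  rownames(subclones) <- NULL
  class(subclones) <- unique(c("lineage_table", class(subclones)))
  list(division = division, subclones = subclones)
}

#' Projection-subtype calls from Ctip2/Satb2 levels
#'
#' Pyramidal cells are subclassified from the relative expression of the
#' transcription factors Ctip2 and Satb2, jointly with laminar position:
#' in layer V, Ctip2-high/Satb2-low cells are subcerebral projection neurons
#' (SCPN), high/high are heterogeneous projection neurons (HPN) and
#' low/high are cortico-cortical (CCPN); in layer VI, high/low cells are
#' cortico-thalamic (CThPN), Ctip2-low cells (whatever the Satb2 level) are
#' CCPN, and high/high cells are left unclassified; in layers II/III and IV
#' only the canonical low/high combination is assigned (CCPN), any other
#' combination is left unclassified.
#'
#' @param layer character vector over `"II/III"`, `"IV"`, `"V"`, `"VI"`.
#' @param ctip2,satb2 character vectors over `"high"`/`"low"`.
#' @return factor with levels `CCPN`, `SCPN`, `HPN`, `CThPN`,
#'   `unclassified`.
#' @export
classify_projection_subtype <- function(layer, ctip2, satb2) {
  stopifnot(all(layer %in% c("II/III", "IV", "V", "VI")),
            all(ctip2 %in% c("high", "low")),
            all(satb2 %in% c("high", "low")))
  n <- max(length(layer), length(ctip2), length(satb2))
  layer <- rep_len(layer, n); ctip2 <- rep_len(ctip2, n)
  satb2 <- rep_len(satb2, n)
  out <- rep("unclassified", n)
  v <- layer == "V"
  out[v & ctip2 == "high" & satb2 == "low"] <- "SCPN"
  out[v & ctip2 == "high" & satb2 == "high"] <- "HPN"
  out[v & ctip2 == "low" & satb2 == "high"] <- "CCPN"
  vi <- layer == "VI"
  out[vi & ctip2 == "high" & satb2 == "low"] <- "CThPN"
  out[vi & ctip2 == "low"] <- "CCPN"
  sup <- layer %in% c("II/III", "IV")
  out[sup & ctip2 == "low" & satb2 == "high"] <- "CCPN"
  factor(out, levels = c("CCPN", "SCPN", "HPN", "CThPN", "unclassified"))
}
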