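#' Progenitor specification for the sequential simulator
#'
#' A progenitor type is defined by, per layer in generation (inside-out)
#' order VI, V, IV, II/III: the maximum number of opportunities `M`
#' (positive integers; the number of stochastic decisions available is
#' drawn uniformly on `1..M`), the generation probability `P` (chance a
#' neuron is actually produced at each decision), plus a per-opportunity
#' interruption probability `q` (chance the whole lineage terminates at an
#' opportunity, emulating premature terminal division or progenitor death)
#' and the population share `fraction`.
#'
#' @param M named or positional integer vector of length 4, order
#'   `l6, l5, l4, l23`.
#' @param P generation probabilities in `[0, 1]`, same order.
#' @param q interruption probability per opportunity in `[0, 1]`.
#' @param fraction population share in `[0, 1]`.
#' @return list of class `progenitor_spec`.
#' @export
progenitor_spec <- function(M, P, q = 0, fraction = 1) {
  M <- .as_gen_vec(M, "M"); P <- .as_gen_vec(P, "P")
  stopifnot(all(M >= 1L), all(M == floor(M)),
            all(P >= 0), all(P <= 1),
            q >= 0, q <= 1, fraction >= 0, fraction <= 1)
  structure(list(M = as.integer(M), P = P, q = q, fraction = fraction),
            class = c("progenitor_spec", "list"))
}

.as_gen_vec <- function(v, what) {
  stopifnot(length(v) == 4L)
  if (!is.null(names(v))) {
    if (!setequal(names(v), .gen_layers)) {
      stop(what, " must be named over ", paste(.gen_layers, collapse = ", "),
           call. = FALSE)
    }
    v <- v[.gen_layers]
  } else {
    names(v) <- .gen_layers
  }
  v
}

#' Model specification for the sequential simulator
#'
#' One progenitor type defines Model 1 (a single equipotent population);
#' two types define Model 2 (a majority population plus a second population
#' with its own generation probabilities and share). Fractions must sum
#' to 1.
#'
#' @param types list of [progenitor_spec()] (length 1 or 2 in the standard
#'   models; any length >= 1 accepted).
#' @param n_progenitors progenitors per simulation repeat (default 100).
#' @param n_repeats number of simulation repeats (default 100).
#' @param size_filter inclusive clone-size bounds applied to each repeat
#'   (default `c(3, 12)`); `NULL` to disable.
#' @param seed integer seed.
#' @return list of class `sim_model_spec`.
#' @export
sim_model_spec <- function(types, n_progenitors = 100L, n_repeats = 100L,
                           size_filter = c(3L, 12L), seed = 1L) {
  if (inherits(types, "progenitor_spec")) types <- list(types)
  stopifnot(length(types) >= 1L,
            all(vapply(types, inherits, logical(1L), "progenitor_spec")),
            n_progenitors >= 1L, n_repeats >= 1L)
  fr <- vapply(types, `[[`, numeric(1L), "fraction")
  if (abs(sum(fr) - 1) > 1e-8) {
    stop("population fractions must sum to 1 (got ", sum(fr), ")",
         call. = FALSE)
  }
  structure(list(types = types, n_progenitors = as.integer(n_progenitors),
                 n_repeats = as.integer(n_repeats),
                 size_filter = size_filter, seed = as.integer(seed)),
            class = c("sim_model_spec", "list"))
}

#' Simulate one lineage sequentially
#'
#' Literal sequential implementation of the generative process: layers are
#' visited in the inside-out order VI, V, IV, II/III; in each layer the
#' number of opportunities is drawn uniformly on `1..M[j]`; at each
#' opportunity, the lineage is first interrupted with probability `q`
#' (terminating all remaining generation), otherwise a neuron is added
#' with probability `P[j]`.
#'
#' This is the reference implementation used for validation;
#' [simulate_model()] uses an exactly equivalent vectorised engine (the
#' index of the first interrupting opportunity is geometric).
#'
#' @param spec a [progenitor_spec()].
#' @return list with `counts` (named integer vector over `l23, l4, l5,
#'   l6`) and `interrupted` (logical).
#' @export
simulate_lineage <- function(spec) {
  counts <- stats::setNames(integer(4L), .gen_layers)
  interrupted <- FALSE
  for (j in seq_along(.gen_layers)) {
    n_opp <- sample.int(spec$M[j], 1L)
    for (o in seq_len(n_opp)) {
      if (spec$q > 0 && stats::runif(1L) < spec$q) {
        interrupted <- TRUE
        break
      }
      if (stats::runif(1L) < spec$P[j]) {
        counts[j] <- counts[j] + 1L
      }
    }
    if (interrupted) break
  }
  list(counts = counts[.disp_layers], interrupted = interrupted)
}

## Vectorised engine: layer counts for `n` progenitors of one type.
## Equivalence with the sequential loop: each opportunity interrupts
## independently with probability q before the generation attempt, so the
## index T of the first interrupting opportunity (over the concatenated
## opportunity sequence) is Geometric(q); opportunities 1..T-1 run their
## generation attempt. Counts are then Binomial over the surviving
## opportunities in each layer.
.simulate_type_counts <- function(spec, n) {
  n_opp <- vapply(seq_len(4L),
                  function(j) sample.int(spec$M[j], n, replace = TRUE),
                  integer(n))
  n_opp <- matrix(n_opp, nrow = n)  # n x 4, generation order
  survived <- if (spec$q > 0) stats::rgeom(n, spec$q) else rep(Inf, n)
  cum_before <- cbind(0, t(apply(n_opp, 1L, cumsum)))[, 1:4, drop = FALSE]
  avail <- pmax(pmin(n_opp, survived - cum_before), 0)
  counts <- matrix(stats::rbinom(4L * n, as.vector(avail),
                                 rep(spec$P, each = n)), nrow = n)
  colnames(counts) <- .gen_layers
  interrupted <- survived < rowSums(n_opp)
  list(counts = counts, interrupted = interrupted)
}

#' Run the sequential lineage-generation model
#'
#' For each of `n_repeats` repeats, assigns `n_progenitors` progenitors to
#' the population types by their fractions, simulates each lineage, and
#' applies the clone-size filter. Each repeat is an independent replicate
#' dataset, as used for model-data z-score comparisons.
#'
#' @param spec a [sim_model_spec()].
#' @param keep_truth record the true type and interruption flag of every
#'   progenitor (before filtering) in the `truth` attribute.
#' @return list of lineage tables (`method = "simulated"`), one per
#'   repeat. With `keep_truth = TRUE`, each carries a `truth` attribute
#'   (data frame: `progenitor`, `true_type`, `interrupted`, `size`,
#'   `kept`).
#' @export
simulate_model <- function(spec, keep_truth = FALSE) {
  n_types <- length(spec$types)
  fr <- vapply(spec$types, `[[`, numeric(1L), "fraction")
  with_master_seed(spec$seed, {
    lapply(seq_len(spec$n_repeats), function(rep_i) {
      n <- spec$n_progenitors
      type_of <- if (n_types == 1L) rep(1L, n) else
        sample.int(n_types, n, replace = TRUE, prob = fr)
      counts <- matrix(0L, n, 4L, dimnames = list(NULL, .gen_layers))
      interrupted <- logical(n)
      for (k in seq_len(n_types)) {
        rows <- which(type_of == k)
        if (length(rows) == 0L) next
        sim <- .simulate_type_counts(spec$types[[k]], length(rows))
        counts[rows, ] <- sim$counts
        interrupted[rows] <- sim$interrupted
      }
      out <- data.frame(
        lineage_id = sprintf("r%03d.p%04d", rep_i, seq_len(n)),
        method = "simulated", area = "model", age = "model",
        stringsAsFactors = FALSE)
      out[.disp_layers] <- counts[, .disp_layers]
      out <- lineage_table(out)
      sizes <- lineage_sizes(out)
      kept <- if (is.null(spec$size_filter)) rep(TRUE, n) else
        sizes >= spec$size_filter[1L] & sizes <= spec$size_filter[2L]
      res <- out[kept, , drop = FALSE]
      if (keep_truth) {
        attr(res, "truth") <- data.frame(
          progenitor = seq_len(n), true_type = type_of,
          interrupted = interrupted, size = sizes, kept = kept)
      }
      res
    })
  })
}

#' Per-layer opportunity caps from experimental data
#'
#' The default cap on opportunities per layer is the maximum number of
#' cells found for that layer in any single experimental lineage across
#' the pooled datasets.
#'
#' @param ... one or more lineage tables.
#' @return named integer vector over `l6, l5, l4, l23`.
#' @export
opportunity_caps <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1L)
  m <- do.call(rbind, lapply(tabs, function(x)
    as.matrix(x[, .gen_layers, drop = FALSE])))
  caps <- pmax(apply(m, 2L, max), 1L)
  stats::setNames(as.integer(caps), .gen_layers)
}

## Statistic vector tracked by the fitter for one simulated repeat.
.fit_stat_vector <- function(x, size_range, with_classes) {
  n <- nrow(x)
  if (n == 0L) return(NULL)
  lf <- laminar_fractions(x)
  h <- size_histogram(x, size_range)
  hv <- as.numeric(h) / n
  out <- c(stats::setNames(as.numeric(lf), paste0("frac_", names(lf))),
           stats::setNames(hv, paste0("size_", names(h))))
  if (with_classes) {
    cf <- class_fractions(x)
    out <- c(out, stats::setNames(as.numeric(cf),
                                  paste0("class_", names(cf))))
  }
  out
}

## Objective: sum of squared z-scores over the tracked statistics for a
## candidate spec, using a fixed evaluation seed (common random numbers).
.fit_objective <- function(spec, target_vec, size_range, with_classes,
                           eval_seed, sd_floor = 1e-3) {
  spec$seed <- eval_seed
  reps <- simulate_model(spec)
  stats_m <- vapply(reps, function(r) {
    v <- .fit_stat_vector(r, size_range, with_classes)
    if (is.null(v)) rep(NA_real_, length(target_vec)) else v
  }, numeric(length(target_vec)))
  stats_m <- t(stats_m)
  if (all(is.na(stats_m))) return(list(value = Inf, z = NULL))
  m <- colMeans(stats_m, na.rm = TRUE)
  s <- pmax(apply(stats_m, 2L, stats::sd, na.rm = TRUE), sd_floor)
  z <- abs(m - target_vec) / s
  list(value = sum(z^2), z = z)
}

#' Fit generation probabilities to target summaries
#'
#' Tunes the free parameters of a simulator template (per-layer generation
#' probabilities, interruption probability and, with two populations, the
#' population share) to match target summary statistics: the four laminar
#' fractions, the clone-size histogram (as per-repeat fractions over the
#' size range) and, when supplied, the three laminar-class fractions. The
#' objective is the sum of squared model-data z-scores over these
#' statistics; the search is a seeded coordinate descent with shrinking
#' step size, using common random numbers (a fixed evaluation seed) so
#' that candidate comparisons are not drowned in simulation noise. The
#' number of populations and the opportunity caps `M` are fixed by the
#' template.
#'
#' @param target list with `laminar_fractions` (4 values summing to 1),
#'   `size_histogram` (counts or fractions over `size_range`, normalised
#'   internally), optional `class_fractions` (3 values summing to 1).
#'   A [summarize_lineages()] result works directly.
#' @param template a [sim_model_spec()] providing the starting point.
#' @param size_range inclusive clone-size range tracked (default 3-12,
#'   matching the template's filter).
#' @param n_eval_repeats simulation repeats per objective evaluation
#'   (default 40; the final report uses the template's `n_repeats`).
#' @param max_cycles coordinate-descent cycles (default 40).
#' @param step initial step size on probabilities (default 0.15).
#' @param min_step stop when the step shrinks below this (default 0.01).
#' @param fit_q,fit_fraction tune the interruption probability / the
#'   population share (defaults `TRUE`).
#' @param seed integer seed for the evaluation stream.
#' @return list of class `sim_fit`: `spec` (fitted [sim_model_spec()]),
#'   `objective_trace`, `z` (final per-statistic z-scores at the
#'   template's full `n_repeats`), `target` (the tracked target vector).
#' @export
fit_model <- function(target, template, size_range = c(3L, 12L),
                      n_eval_repeats = 40L, max_cycles = 40L, step = 0.15,
                      min_step = 0.01, fit_q = TRUE, fit_fraction = TRUE,
                      seed = 1L) {
  lf <- target$laminar_fractions
  if (is.null(lf) || length(lf) != 4L || abs(sum(lf) - 1) > 1e-6) {
    stop("target laminar fractions must be 4 values summing to 1",
         call. = FALSE)
  }
  if (is.null(names(lf))) names(lf) <- .disp_layers
  h <- target$size_histogram
  sizes <- seq.int(size_range[1L], size_range[2L])
  if (is.null(h) || length(h) != length(sizes)) {
    stop("target size histogram must cover sizes ",
         size_range[1L], "..", size_range[2L], call. = FALSE)
  }
  hv <- as.numeric(h) / sum(h)
  with_classes <- !is.null(target$class_fractions)
  target_vec <- c(stats::setNames(as.numeric(lf[.disp_layers]),
                                  paste0("frac_", .disp_layers)),
                  stats::setNames(hv, paste0("size_", sizes)))
  if (with_classes) {
    cf <- target$class_fractions
    if (abs(sum(cf) - 1) > 1e-6) {
      stop("target class fractions must sum to 1", call. = FALSE)
    }
    target_vec <- c(target_vec, stats::setNames(
      as.numeric(cf), paste0("class_", c("translaminar", "deep_restricted",
                                         "superficial_restricted"))))
  }

  eval_seed <- stage_seed(seed, "fit-eval")
  n_types <- length(template$types)
  cur <- template
  cur$n_repeats <- as.integer(n_eval_repeats)

  ## flatten/unflatten the free parameters
  get_par <- function(sp) {
    v <- unlist(lapply(sp$types, function(ty) ty$P))
    if (fit_q) v <- c(v, vapply(sp$types, `[[`, numeric(1L), "q"))
    if (fit_fraction && n_types >= 2L) {
      v <- c(v, vapply(sp$types[-n_types], `[[`, numeric(1L), "fraction"))
    }
    v
  }
  set_par <- function(sp, v) {
    pos <- 1L
    for (k in seq_len(n_types)) {
      sp$types[[k]]$P[] <- pmin(pmax(v[pos:(pos + 3L)], 0), 1)
      pos <- pos + 4L
    }
    if (fit_q) {
      for (k in seq_len(n_types)) {
        sp$types[[k]]$q <- pmin(pmax(v[pos], 0), 0.5)
        pos <- pos + 1L
      }
    }
    if (fit_fraction && n_types >= 2L) {
      fr <- pmin(pmax(v[pos:(pos + n_types - 2L)], 0.01), 0.99)
      for (k in seq_len(n_types - 1L)) sp$types[[k]]$fraction <- fr[k]
      sp$types[[n_types]]$fraction <- 1 - sum(fr)
      pos <- pos + n_types - 1L
    }
    sp
  }

  par <- get_par(cur)
  best <- .fit_objective(set_par(cur, par), target_vec, size_range,
                         with_classes, eval_seed)
  trace <- best$value
  st <- step
  for (cycle in seq_len(max_cycles)) {
    improved <- FALSE
    for (d in seq_along(par)) {
      for (dir in c(1, -1)) {
        cand <- par
        cand[d] <- cand[d] + dir * st
        val <- .fit_objective(set_par(cur, cand), target_vec, size_range,
                              with_classes, eval_seed)
        if (val$value < best$value) {
          par <- cand
          best <- val
          improved <- TRUE
          break
        }
      }
    }
    trace <- c(trace, best$value)
    if (!improved) {
      st <- st / 2
      if (st < min_step) break
    }
  }

  fitted <- set_par(template, par)
  fitted$seed <- template$seed
  final <- .fit_objective(fitted, target_vec, size_range, with_classes,
                          stage_seed(seed, "fit-final"))
  structure(list(spec = fitted, objective_trace = trace, z = final$z,
                 objective = final$value, target = target_vec),
            class = c("sim_fit", "list"))
}

#' @export
print.sim_fit <- function(x, ...) {
  cat("Sequential-model fit: final objective ",
      round(x$objective, 3), "\n", sep = "")
  cat("  max |z| over tracked statistics: ", round(max(x$z), 3), "\n",
      sep = "")
  for (k in seq_along(x$spec$types)) {
    ty <- x$spec$types[[k]]
    cat("  type ", k, ": fraction ", round(ty$fraction, 3), ", q ",
        round(ty$q, 3), ", P(VI,V,IV,II/III) = ",
        paste(round(ty$P, 3), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
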