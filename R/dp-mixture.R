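#' Occupancy matrix from a lineage table
#'
#' Extracts the N x 4 count matrix S whose element `S[i, j]` is the number
#' of neurons of lineage i in layer j, with columns in the canonical
#' inside-out generation order VI, V, IV, II/III.
#'
#' @param x lineage table.
#' @return integer matrix with column names `l6, l5, l4, l23`.
#' @export
occupancy_matrix <- function(x) {
  m <- as.matrix(x[, .gen_layers, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- if ("lineage_id" %in% names(x)) x$lineage_id else NULL
  m
}

#' Censoring mask over terminal superficial zeros
#'
#' Zero counts in the most superficial layers of a clone may be spurious:
#' an external process (premature terminal division, progenitor death) can
#' stop a lineage before its superficial layers are produced. The mask
#' therefore excludes, for each lineage, the most superficial empty layers
#' not followed (more superficially) by an occupied layer: scanning from
#' II/III toward VI, sigma is 0 for each empty layer until the first
#' occupied layer is reached, and 1 for every layer from there on. A fully
#' empty row is fully masked and reported via the `masked_rows` attribute
#' (with a warning); such rows contribute only prior terms to inference.
#'
#' @param S occupancy matrix in generation order (see
#'   [occupancy_matrix()]).
#' @return binary matrix sigma of the same shape, attribute `masked_rows`
#'   listing fully masked row indices.
#' @export
selection_mask <- function(S) {
  S <- as.matrix(S)
  n <- nrow(S)
  sig <- matrix(1L, n, ncol(S), dimnames = dimnames(S))
  ## columns are generation order l6..l23; scan superficial -> deep,
  ## i.e. from the last column backwards
  for (i in seq_len(n)) {
    for (j in rev(seq_len(ncol(S)))) {
      if (S[i, j] > 0L) break
      sig[i, j] <- 0L
    }
  }
  masked <- which(rowSums(S) == 0L)
  if (length(masked) > 0L) {
    warning(length(masked), " all-zero lineage(s) fully masked; they ",
            "contribute only prior terms", call. = FALSE)
  }
  attr(sig, "masked_rows") <- masked
  sig
}

#' Joint log-likelihood of the binomial mixture
#'
#' Evaluates log P(t, S | p, f) = sum_t n_t log f_t +
#' sum_ij sigma_ij [ S_ij log p_{t_i j} + (N_max - S_ij) log(1 - p_{t_i j}) ].
#' The binomial coefficient is omitted, exactly as in the model definition;
#' it is constant given S and N_max so the posterior over (t, p, f, K) is
#' unaffected. A probability of exactly 0 or 1 contradicted by a count
#' yields `-Inf` (never an error); a consistent extreme (e.g. p = 1 with
#' S = N_max) contributes 0.
#'
#' @param S occupancy matrix (N x 4, generation order).
#' @param sigma censoring mask from [selection_mask()].
#' @param t integer type assignments in `1..K`.
#' @param p K x 4 matrix of per-type layer-occupancy probabilities.
#' @param f length-K type frequencies (positive for occupied types).
#' @param n_max binomial cap per layer (default 20).
#' @return scalar log-likelihood.
#' @export
dp_log_likelihood <- function(S, sigma, t, p, f, n_max = 20L) {
  S <- as.matrix(S); sigma <- as.matrix(sigma); p <- rbind(p)
  stopifnot(nrow(S) == length(t), all(dim(S) == dim(sigma)),
            max(t) <= nrow(p), length(f) >= max(t), all(S <= n_max))
  nt <- tabulate(t, nbins = length(f))
  ll <- sum(nt[nt > 0] * log(f[nt > 0]))
  P <- p[t, , drop = FALSE]
  term <- function(w, prob_log) {
    ## w * log(prob): 0 * -Inf counts as 0 (factor absent)
    v <- w * prob_log
    v[w == 0] <- 0
    v
  }
  ll + sum(sigma * (term(S, log(P)) + term(n_max - S, log1p(-P))))
}

#' Configuration for the Gibbs sampler
#'
#' @param n_draws retained posterior draws (default 4000).
#' @param burn_in discarded initial sweeps (default 1000).
#' @param thinning keep every `thinning`-th sweep after burn-in.
#' @param n_max binomial cap on neurons per layer per lineage (default 20).
#' @param beta_a,beta_b Beta prior on occupancy probabilities (default the
#'   flat Beta(1,1)).
#' @param alpha Dirichlet-process concentration (default 1).
#' @param n_aux number of auxiliary (fresh candidate) components per
#'   assignment update (default 3).
#' @param seed integer seed.
#' @return list of class `gibbs_config`.
#' @export
gibbs_config <- function(n_draws = 4000L, burn_in = 1000L, thinning = 1L,
                         n_max = 20L, beta_a = 1, beta_b = 1, alpha = 1,
                         n_aux = 3L, seed = 1L) {
  stopifnot(n_draws >= 1L, burn_in >= 0L, thinning >= 1L, n_max >= 1L,
            beta_a > 0, beta_b > 0, alpha > 0, n_aux >= 1L)
  structure(list(n_draws = as.integer(n_draws),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning), n_max = as.integer(n_max),
                 beta_a = beta_a, beta_b = beta_b, alpha = alpha,
                 n_aux = as.integer(n_aux), seed = as.integer(seed)),
            class = c("gibbs_config", "list"))
}

## Internal mutable sampler state: list(t, K, nt, p, lp, lq).
## lp = log(p), lq = log1p(-p), kept in sync with p.
.state_init <- function(S, sigma, cfg) {
  n <- nrow(S)
  p <- matrix(stats::rbeta(4L, cfg$beta_a, cfg$beta_b), 1L, 4L)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  list(t = rep(1L, n), K = 1L, nt = n,
       p = p, lp = log(p), lq = log1p(-p))
}

#' One Gibbs sweep of the Dirichlet-process binomial mixture
#'
#' Performs one full sweep of the auxiliary-component (algorithm-8 style)
#' sampler: (i) each assignment `t_i` is resampled from its conditional
#' under the Chinese-restaurant-process prior, with `n_aux` fresh candidate
#' types carrying Beta-prior draws of p, so existing classes can be removed
#' and new ones introduced; (ii) each occupied type's occupancy
#' probabilities are resampled from their conjugate posterior
#' Beta(a + sum sigma S, b + sum sigma (N_max - S)). Empty types are pruned
#' and K updated. Type frequencies are implicit CRP weights
#' `n_t / (N + alpha)`.
#'
#' Exposed mainly for testing and custom schedules; use [run_inference()]
#' for a complete run.
#'
#' @param state sampler state as returned by a previous sweep (or built
#'   internally by [run_inference()]).
#' @param S,sigma occupancy matrix and censoring mask.
#' @param cfg a [gibbs_config()].
#' @return updated state (list with `t`, `K`, `nt`, `p`).
#' @export
gibbs_sweep <- function(state, S, sigma, cfg) {
  n <- nrow(S)
  SS <- sigma * S
  SF <- sigma * (cfg$n_max - S)
  m <- cfg$n_aux
  log_alpha_m <- log(cfg$alpha / m)
  t <- state$t; K <- state$K; nt <- state$nt
  p <- state$p; lp <- state$lp; lq <- state$lq
  for (i in seq_len(n)) {
    ti <- t[i]
    nt[ti] <- nt[ti] - 1L
    reuse_p <- NULL
    if (nt[ti] == 0L) {
      ## delete the emptied type, retaining its parameters: they become
      ## the first auxiliary candidate (algorithm-8 bookkeeping; dropping
      ## them would bias the stationary distribution)
      reuse_p <- p[ti, , drop = FALSE]
      if (ti != K) {
        t[t == K] <- ti
        nt[ti] <- nt[K]
        p[ti, ] <- p[K, ]; lp[ti, ] <- lp[K, ]; lq[ti, ] <- lq[K, ]
      }
      K <- K - 1L
      nt <- nt[seq_len(K)]
      p <- p[seq_len(K), , drop = FALSE]
      lp <- lp[seq_len(K), , drop = FALSE]
      lq <- lq[seq_len(K), , drop = FALSE]
    }
    ## auxiliary candidates: fresh prior draws (plus the retained
    ## singleton parameters, when a type was just emptied)
    n_fresh <- if (is.null(reuse_p)) m else m - 1L
    paux <- matrix(stats::rbeta(4L * n_fresh, cfg$beta_a, cfg$beta_b),
                   n_fresh, 4L)
    if (!is.null(reuse_p)) paux <- rbind(reuse_p, paux)
    paux <- pmin(pmax(paux, 1e-12), 1 - 1e-12)
    ssi <- SS[i, ]; sfi <- SF[i, ]
    logw <- c(log(nt) + lp %*% ssi + lq %*% sfi,
              log_alpha_m + log(paux) %*% ssi + log1p(-paux) %*% sfi)
    w <- exp(logw - max(logw))
    choice <- sample.int(K + m, 1L, prob = w)
    if (choice <= K) {
      t[i] <- choice
      nt[choice] <- nt[choice] + 1L
    } else {
      aux_idx <- choice - K
      K <- K + 1L
      t[i] <- K
      nt <- c(nt, 1L)
      newp <- paux[aux_idx, , drop = FALSE]
      p <- rbind(p, newp)
      lp <- rbind(lp, log(newp))
      lq <- rbind(lq, log1p(-newp))
    }
  }
  ## conjugate update of occupancy probabilities per occupied type
  for (k in seq_len(K)) {
    rows <- t == k
    a_post <- cfg$beta_a + colSums(SS[rows, , drop = FALSE])
    b_post <- cfg$beta_b + colSums(SF[rows, , drop = FALSE])
    pk <- stats::rbeta(4L, a_post, b_post)
    pk <- pmin(pmax(pk, 1e-12), 1 - 1e-12)
    p[k, ] <- pk
    lp[k, ] <- log(pk)
    lq[k, ] <- log1p(-pk)
  }
  list(t = t, K = K, nt = nt, p = p, lp = lp, lq = lq)
}

#' Posterior inference on the number of progenitor types
#'
#' Fits the Dirichlet-process binomial mixture to a lineage table or
#' occupancy matrix: applies [selection_mask()], initialises a single type
#' with prior-drawn occupancy probabilities, runs `burn_in + n_draws *
#' thinning` Gibbs sweeps and records the post-burn-in draws. Reproducible
#' under the config seed.
#'
#' @param x lineage table or an N x 4 occupancy matrix in generation order.
#' @param config a [gibbs_config()].
#' @return object of class `dp_posterior`: list with `K` (integer vector of
#'   occupied-type counts per draw), `t` (draws x N assignment matrix),
#'   `p` (list of K x 4 matrices), `f` (list of frequency vectors,
#'   `n_t / N`), `loglik` (trace), `S`, `sigma`, `config`.
#' @export
run_inference <- function(x, config = gibbs_config()) {
  S <- if (is.matrix(x)) x else occupancy_matrix(x)
  if (any(S > config$n_max)) {
    stop("occupancy count exceeds n_max = ", config$n_max,
         " (rows ", paste(which(rowSums(S > config$n_max) > 0),
                          collapse = ", "), ")", call. = FALSE)
  }
  sigma <- selection_mask(S)
  n <- nrow(S)
  n_keep <- config$n_draws
  draws_K <- integer(n_keep)
  draws_t <- matrix(NA_integer_, n_keep, n)
  draws_p <- vector("list", n_keep)
  draws_f <- vector("list", n_keep)
  loglik <- numeric(n_keep)
  with_master_seed(config$seed, {
    state <- .state_init(S, sigma, config)
    total <- config$burn_in + n_keep * config$thinning
    kept <- 0L
    for (sweep in seq_len(total)) {
      state <- gibbs_sweep(state, S, sigma, config)
      if (sweep > config$burn_in &&
          (sweep - config$burn_in) %% config$thinning == 0L) {
        kept <- kept + 1L
        draws_K[kept] <- state$K
        draws_t[kept, ] <- state$t
        draws_p[[kept]] <- state$p
        f <- state$nt / n
        draws_f[[kept]] <- f
        loglik[kept] <- dp_log_likelihood(S, sigma, state$t, state$p, f,
                                          config$n_max)
      }
    }
  })
  structure(list(K = draws_K, t = draws_t, p = draws_p, f = draws_f,
                 loglik = loglik, S = S, sigma = sigma, config = config),
            class = c("dp_posterior", "list"))
}

#' Posterior distribution over the number of progenitor types
#'
#' Normalised frequencies of the number of occupied types K across
#' posterior draws; the fraction of draws that demand each particular
#' number of progenitor identities.
#'
#' @param samples a `dp_posterior` from [run_inference()].
#' @return named numeric vector over observed K values, summing to 1.
#' @export
progenitor_count_distribution <- function(samples) {
  if (length(samples$K) == 0L) stop("no posterior draws", call. = FALSE)
  tab <- table(samples$K)
  c(tab) / length(samples$K)
}

#' Posterior-predictive lineage simulation
#'
#' Simulates new lineages from the fitted mixture: for each lineage a
#' posterior draw is picked uniformly, a type is drawn by its frequencies,
#' each layer count is drawn Binomial(N_max, p), and the clone-size filter
#' is applied. Output uses the standard lineage-table schema with
#' `method = "simulated"`.
#'
#' @param samples a `dp_posterior`.
#' @param n_lineages number of lineages to draw before filtering.
#' @param size_filter inclusive size bounds applied after simulation
#'   (default `c(3, 12)`); `NULL` to disable.
#' @param seed integer seed.
#' @return a [lineage_table()] (possibly with fewer than `n_lineages`
#'   rows after filtering).
#' @export
posterior_predictive <- function(samples, n_lineages, size_filter = c(3L, 12L),
                                 seed = 1L) {
  stopifnot(length(samples$K) >= 1L, n_lineages >= 1L)
  n_max <- samples$config$n_max
  counts <- with_master_seed(seed, {
    idx <- sample.int(length(samples$K), n_lineages, replace = TRUE)
    t(vapply(idx, function(d) {
      f <- samples$f[[d]]
      k <- sample.int(length(f), 1L, prob = f)
      stats::rbinom(4L, n_max, samples$p[[d]][k, ])
    }, integer(4L)))
  })
  colnames(counts) <- .gen_layers
  out <- data.frame(lineage_id = sprintf("pp%05d", seq_len(n_lineages)),
                    method = "simulated", area = "model", age = "model",
                    stringsAsFactors = FALSE)
  out[.disp_layers] <- counts[, .disp_layers]
  out <- lineage_table(out)
  if (!is.null(size_filter)) {
    out <- neurogenic_filter(out, size_filter[1L], size_filter[2L])
  }
  out
}

#' @export
print.dp_posterior <- function(x, ...) {
  cat("Dirichlet-process binomial mixture posterior\n")
  cat("  lineages: ", nrow(x$S), ", draws: ", length(x$K), "\n", sep = "")
  pk <- progenitor_count_distribution(x)
  cat("  P(K):", paste(sprintf("K=%s: %.3f", names(pk), pk),
                       collapse = ", "), "\n")
  invisible(x)
}
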