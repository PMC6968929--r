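test_that("selection mask censors terminal superficial zeros only", {
  ## rows given in generation order l6, l5, l4, l23
  S <- rbind(c(3, 2, 0, 0),   # l23, l4 empty and terminal -> masked
             c(2, 0, 1, 0),   # l23 terminal zero masked; l5 zero kept
             c(1, 1, 1, 1),   # fully occupied
             c(0, 0, 0, 5))   # l23 occupied: nothing masked
  colnames(S) <- c("l6", "l5", "l4", "l23")
  sig <- selection_mask(S)
  expect_equal(unname(sig), rbind(c(1, 1, 0, 0),
                                  c(1, 1, 1, 0),
                                  c(1, 1, 1, 1),
                                  c(1, 1, 1, 1)), ignore_attr = TRUE)
  expect_length(attr(sig, "masked_rows"), 0L)

  expect_warning(sig0 <- selection_mask(matrix(0L, 2, 4)), "masked")
  expect_true(all(sig0 == 0L))
  expect_equal(attr(sig0, "masked_rows"), 1:2)
})

test_that("log-likelihood matches direct evaluation of the formula", {
  ## independent oracle: literal triple sum over types, lineages, layers
  oracle <- function(S, sig, t, p, f, n_max) {
    nt <- tabulate(t, length(f))
    tot <- sum(ifelse(nt > 0, nt * log(f), 0))
    for (i in seq_len(nrow(S))) {
      for (j in seq_len(4L)) {
        if (sig[i, j] == 1) {
          tot <- tot + S[i, j] * log(p[t[i], j]) +
            (n_max - S[i, j]) * log(1 - p[t[i], j])
        }
      }
    }
    tot
  }

  ## printed-formula spot value: one lineage (1,1,1,1), p = 0.5, f = 1
  S1 <- matrix(1L, 1, 4); sg1 <- matrix(1L, 1, 4)
  expect_equal(dp_log_likelihood(S1, sg1, 1L, matrix(0.5, 1, 4), 1, 20),
               80 * log(0.5), tolerance = 1e-12)

  ## random small cases against the oracle
  set.seed(23)
  for (rep_i in 1:20) {
    n <- sample(2:6, 1); k <- sample(1:3, 1)
    S <- matrix(sample(0:20, n * 4, TRUE), n, 4)
    sig <- matrix(rbinom(n * 4, 1, 0.8), n, 4)
    t <- sample(seq_len(k), n, TRUE)
    t[seq_len(k)] <- seq_len(k)  # every type occupied
    p <- matrix(runif(k * 4, 0.05, 0.95), k, 4)
    f <- as.numeric(prop.table(runif(k) + 0.1))
    expect_equal(dp_log_likelihood(S, sig, t, p, f, 20),
                 oracle(S, sig, t, p, f, 20), tolerance = 1e-9)
  }

  ## mask removes all count terms; with K = 1, f = 1 the value is exactly 0
  S <- matrix(5L, 3, 4)
  expect_equal(dp_log_likelihood(S, matrix(0L, 3, 4), rep(1L, 3),
                                 matrix(0.3, 1, 4), 1, 20), 0)

  ## consistent extremes contribute 0; contradicted extremes give -Inf
  S20 <- matrix(20L, 1, 4)
  expect_equal(dp_log_likelihood(S20, matrix(1L, 1, 4), 1L,
                                 matrix(1, 1, 4), 1, 20), 0)
  expect_identical(dp_log_likelihood(S1, matrix(1L, 1, 4), 1L,
                                     matrix(0, 1, 4), 1, 20), -Inf)
})

test_that("log-likelihood is invariant under type relabelling", {
  set.seed(29)
  S <- matrix(sample(0:20, 24, TRUE), 6, 4)
  sig <- matrix(1L, 6, 4)
  t <- c(1L, 2L, 3L, 1L, 2L, 3L)
  p <- matrix(runif(12, 0.1, 0.9), 3, 4)
  f <- c(0.5, 0.3, 0.2)
  base_ll <- dp_log_likelihood(S, sig, t, p, f, 20)
  for (perm in list(c(2L, 1L, 3L), c(3L, 1L, 2L), c(2L, 3L, 1L))) {
    t2 <- perm[t]
    p2 <- p[order(perm), , drop = FALSE]
    f2 <- f[order(perm)]
    expect_equal(dp_log_likelihood(S, sig, t2, p2, f2, 20), base_ll,
                 tolerance = 1e-9)
  }
})

test_that("sampler visits the CRP prior when all data are masked", {
  ## all-zero occupancy: the mask removes every count term and the
  ## K-distribution must match Chinese-restaurant-process closed forms
  N <- 8; alpha <- 1.5
  S <- matrix(0L, N, 4)
  cfg <- gibbs_config(n_draws = 4000, burn_in = 200, alpha = alpha,
                      seed = 31)
  fit <- suppressWarnings(run_inference(S, cfg))
  crp_mean <- sum(alpha / (alpha + 0:(N - 1)))
  ## batch-means standard error to respect autocorrelation
  batches <- colMeans(matrix(fit$K, nrow = 50))
  se <- stats::sd(batches) / sqrt(length(batches))
  expect_lt(abs(mean(fit$K) - crp_mean), 3 * se)
})

test_that("co-assignment of two lineages matches the exact 2-partition posterior", {
  ## with two lineages the posterior over partitions is computable in
  ## closed form from CRP weights and Beta-binomial marginal likelihoods
  S <- rbind(c(20L, 20L, 20L, 20L), c(0L, 0L, 0L, 20L))
  colnames(S) <- c("l6", "l5", "l4", "l23")
  sig <- selection_mask(S)
  a <- 1; b <- 1; alpha <- 1; n_max <- 20
  ll_tog <- log(1 / (1 + alpha)) +
    marginal_loglik_one_type(S, sig, n_max, a, b)
  ll_apart <- log(alpha / (1 + alpha)) +
    marginal_loglik_one_type(S[1, , drop = FALSE], sig[1, , drop = FALSE],
                             n_max, a, b) +
    marginal_loglik_one_type(S[2, , drop = FALSE], sig[2, , drop = FALSE],
                             n_max, a, b)
  p_together <- 1 / (1 + exp(ll_apart - ll_tog))

  cfg <- gibbs_config(n_draws = 4000, burn_in = 200, alpha = alpha,
                      beta_a = a, beta_b = b, n_max = n_max, seed = 37)
  fit <- run_inference(S, cfg)
  observed <- mean(fit$K == 1L)
  batches <- colMeans(matrix(as.numeric(fit$K == 1L), nrow = 50))
  se <- stats::sd(batches) / sqrt(length(batches))
  expect_lt(abs(observed - p_together), 4 * se + 0.02)

  ## identical extreme rows are overwhelmingly co-assigned
  S_same <- rbind(c(20L, 20L, 20L, 20L), c(20L, 20L, 20L, 20L))
  fit_same <- run_inference(S_same, gibbs_config(n_draws = 2000,
                                                 burn_in = 200, seed = 38))
  expect_gt(mean(fit_same$K == 1L), 0.9)
})

test_that("single-type conjugacy: sampled p matches the Beta posterior mean", {
  set.seed(43)
  S <- matrix(rbinom(40, 20, 0.35), 10, 4)
  S[, 4] <- pmax(S[, 4], 1L)  # keep every row unmasked
  colnames(S) <- c("l6", "l5", "l4", "l23")
  sig <- selection_mask(S)
  ## alpha tiny: the sampler stays at K = 1, isolating the conjugate update
  cfg <- gibbs_config(n_draws = 3000, burn_in = 200, alpha = 1e-8,
                      seed = 47)
  fit <- run_inference(S, cfg)
  expect_true(all(fit$K == 1L))
  p_draws <- t(vapply(fit$p, function(P) P[1, ], numeric(4L)))
  post_mean <- (1 + colSums(sig * S)) / (2 + colSums(sig * 20))
  mc_se <- apply(p_draws, 2, stats::sd) / sqrt(nrow(p_draws) / 20)
  expect_true(all(abs(colMeans(p_draws) - post_mean) < 3 * mc_se + 0.01))
})

test_that("inference recovers two well-separated progenitor types", {
  p_true <- rbind(c(0.4, 0.4, 0.05, 0.05),   # deep-biased type
                  c(0.05, 0.05, 0.4, 0.4))   # superficial-biased type
  g <- generate_occupancy_dataset(2, p_true, c(0.5, 0.5), n = 200,
                                  seed = 53)
  cfg <- gibbs_config(n_draws = 600, burn_in = 200, seed = 59)
  fit <- suppressWarnings(run_inference(g$S, cfg))
  pk <- progenitor_count_distribution(fit)
  expect_equal(names(which.max(pk)), "2")
  expect_equal(sum(pk), 1, tolerance = 1e-12)

  ## posterior mean p per type close to truth (types matched by deep layer)
  k2 <- which(fit$K == 2L)
  pm <- Reduce(`+`, lapply(k2, function(d) {
    P <- fit$p[[d]]
    P[order(P[, 1], decreasing = TRUE), ]
  })) / length(k2)
  expect_true(all(abs(pm - p_true) < 0.05))

  ## determinism under the config seed
  fit2 <- suppressWarnings(run_inference(g$S, cfg))
  expect_identical(fit$K, fit2$K)
  expect_identical(fit$loglik, fit2$loglik)

  ## homogeneous data stay at one type
  g1 <- generate_occupancy_dataset(1, matrix(0.3, 1, 4), 1, n = 100,
                                   seed = 61)
  fit1 <- suppressWarnings(run_inference(g1$S, gibbs_config(
    n_draws = 400, burn_in = 150, seed = 67)))
  pk1 <- progenitor_count_distribution(fit1)
  expect_equal(names(which.max(pk1)), "1")
})

test_that("posterior predictive respects the fitted mixture and filter", {
  ## collapse the posterior by hand to isolate the predictive draw
  collapsed <- function(p_row) {
    structure(list(K = 1L, t = matrix(1L, 1, 1),
                   p = list(matrix(p_row, 1, 4)), f = list(1),
                   loglik = 0, S = matrix(0L, 1, 4),
                   sigma = matrix(0L, 1, 4),
                   config = gibbs_config(seed = 1)),
              class = c("dp_posterior", "list"))
  }
  ## p = 0: all-empty lineages are filtered out entirely
  expect_equal(nrow(posterior_predictive(collapsed(rep(0, 4)), 50)), 0L)
  ## p = 1: every lineage is (20,20,20,20), removed by the 12-cell cap
  expect_equal(nrow(posterior_predictive(collapsed(rep(1, 4)), 50)), 0L)
  full <- posterior_predictive(collapsed(rep(1, 4)), 10, size_filter = NULL)
  expect_true(all(as.matrix(full[, c("l23", "l4", "l5", "l6")]) == 20L))

  ## predictive laminar fractions match the generating p (binomial closed
  ## form: expected layer share = p_j / sum(p))
  p_row <- c(0.6, 0.3, 0.2, 0.1)  # generation order l6, l5, l4, l23
  pred <- posterior_predictive(collapsed(p_row), 4000, size_filter = NULL,
                               seed = 71)
  lf <- laminar_fractions(pred)
  expected <- rev(p_row) / sum(p_row)  # display order l23, l4, l5, l6
  expect_true(all(abs(lf - expected) < 0.01))

  ## inference run with S exceeding n_max is rejected
  expect_error(run_inference(matrix(25L, 2, 4), gibbs_config()), "n_max")
})
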