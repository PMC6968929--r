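test_that("laminar fractions normalise per-layer totals", {
  expect_equal(unname(laminar_fractions(make_lineages(c(1, 1, 1, 1)))),
               rep(0.25, 4))
  expect_equal(unname(laminar_fractions(make_lineages(c(0, 0, 0, 7)))),
               c(0, 0, 0, 1))
  x <- mixed_fixture()
  expect_equal(sum(laminar_fractions(x)), 1, tolerance = 1e-12)
  ## invariant under permutation, any seed
  set.seed(3)
  for (i in 1:5) {
    expect_equal(laminar_fractions(permute_dataset(x)),
                 laminar_fractions(x))
  }
  expect_error(laminar_fractions(x[0, ]), "empty")
})

test_that("size histogram bins clone totals and reports out-of-range", {
  x <- make_lineages(cbind(c(4, 4, 8, 2, 14), 0, 0, 0))
  h <- size_histogram(x)
  expect_equal(h[["4"]], 2L)
  expect_equal(h[["8"]], 1L)
  expect_equal(sum(h), 3L)
  expect_equal(attr(h, "n_below"), 1L)
  expect_equal(attr(h, "n_above"), 1L)
  h0 <- size_histogram(x[0, ])
  expect_true(all(h0 == 0L))
})

test_that("class fractions agree with per-lineage reclassification", {
  x <- mixed_fixture()
  cf <- class_fractions(x)
  expect_equal(sum(cf), 1, tolerance = 1e-12)
  expect_equal(unname(cf), c(3, 1, 1) / 5)

  ## oracle equivalence on a large random synthetic set
  set.seed(47)
  counts <- matrix(rpois(4000, 1.2), ncol = 4)
  counts <- counts[rowSums(counts) > 0, ]
  big <- make_lineages(counts)
  cf_big <- class_fractions(big)
  sup <- rowSums(counts[, 1:2]); dee <- rowSums(counts[, 3:4])
  expect_equal(unname(cf_big),
               c(mean(sup > 0 & dee > 0), mean(sup == 0 & dee > 0),
                 mean(dee == 0 & sup > 0)))
})

test_that("configuration frequencies are consistent with classes", {
  x <- make_lineages(rbind(c(1, 1, 1, 1), c(1, 1, 1, 1)))
  qf <- config_frequencies(x)
  expect_equal(qf[["1111"]], 1)
  expect_equal(sum(qf), 1, tolerance = 1e-12)

  ## restricted-code frequencies sum to the restricted class fractions
  set.seed(53)
  counts <- matrix(rpois(2000, 1), ncol = 4)
  counts <- counts[rowSums(counts) > 0, ]
  big <- make_lineages(counts)
  qf_big <- config_frequencies(big)
  cf_big <- class_fractions(big)
  deep_codes <- grep("^00", config_levels(), value = TRUE)
  sup_codes <- grep("00$", config_levels(), value = TRUE)
  expect_equal(sum(qf_big[deep_codes]),
               unname(cf_big["deep_restricted"]), tolerance = 1e-12)
  expect_equal(sum(qf_big[sup_codes]),
               unname(cf_big["superficial_restricted"]), tolerance = 1e-12)

  ## uniform support sampling approaches 1/15 per code
  idx <- sample(15, 30000, replace = TRUE)
  supports <- expand.grid(l23 = 0:1, l4 = 0:1, l5 = 0:1, l6 = 0:1)
  supports <- as.matrix(supports[rowSums(supports) > 0, ])
  uni <- make_lineages(supports[idx, ])
  expect_true(all(abs(config_frequencies(uni) - 1 / 15) <
                    3 * sqrt((1 / 15) * (14 / 15) / 30000)))
})

test_that("superficial-deep correlation matches a rank-then-Pearson oracle", {
  down <- make_lineages(rbind(c(4, 0, 0, 0), c(3, 0, 1, 0),
                              c(2, 0, 2, 0), c(1, 0, 3, 0)))
  expect_equal(superficial_deep_correlation(down), -1)
  up <- make_lineages(rbind(c(1, 0, 1, 0), c(2, 0, 2, 0), c(3, 0, 3, 0)))
  expect_equal(superficial_deep_correlation(up), 1)

  set.seed(59)
  for (i in 1:100) {
    counts <- matrix(rpois(40, 2), ncol = 4)
    counts[1, ] <- counts[1, ] + 1
    x <- make_lineages(counts)
    s <- rowSums(counts[, 1:2]); d <- rowSums(counts[, 3:4])
    if (stats::var(s) == 0 || stats::var(d) == 0) next
    expect_equal(superficial_deep_correlation(x),
                 stats::cor(rank(s), rank(d)), tolerance = 1e-12)
  }

  const <- make_lineages(rbind(c(1, 0, 1, 0), c(1, 0, 2, 0), c(1, 0, 3, 0)))
  expect_error(superficial_deep_correlation(const), "constant")
})

test_that("subtype diversity counts distinct subclasses in full clones", {
  counts <- rbind(c(2, 1, 1, 1),   # full code, 5 cells
                  c(1, 1, 1, 1),   # full code, 4 cells
                  c(2, 0, 1, 1),   # not full code: excluded from the stat
                  c(1, 1, 1, 2))   # full code, 5 cells, 1 unclassified
  x <- make_lineages(counts,
                     n_ccpn = c(5, 1, 4, 2), n_scpn = c(0, 1, 0, 1),
                     n_cthpn = c(0, 1, 0, 1), n_hpn = c(0, 1, 0, 0))
  d <- subtype_diversity(x)
  ## row 1: one subclass; row 2: four subclasses; row 4 incomplete -> out
  expect_equal(unname(d), c(0.5, 0, 0, 0.5), ignore_attr = TRUE)
  expect_equal(attr(d, "n_included"), 2L)
  expect_equal(attr(d, "n_excluded"), 1L)
  expect_equal(sum(d), 1, tolerance = 1e-12)
})

test_that("z-scores use the sample standard deviation and scale correctly", {
  expect_equal(zscore(2, c(1, 2, 3)), 0)
  expect_equal(zscore(4, c(1, 2, 3)), 2)
  expect_equal(zscore(4 + 10, c(1, 2, 3) + 10), 2)
  expect_equal(zscore(4 * 3, c(1, 2, 3) * 3), 2)
  expect_error(zscore(1, c(2, 2, 2)), "zero")
  expect_error(zscore(1, 2), ">= 2")
})

test_that("categorical comparisons pick the documented test", {
  same <- compare_datasets(c(10, 20, 30), c(10, 20, 30))
  expect_equal(same$statistic, 0)
  expect_equal(same$test, "chi-square")

  ## 2x2 always uses Fisher; p matches hypergeometric enumeration
  fish <- compare_datasets(c(1, 9), c(9, 1))
  expect_equal(fish$test, "fisher")
  ## oracle: enumerate all tables with the same margins
  m <- c(10, 10); k <- 10  # row sums 10/10, first-column total 10
  probs <- vapply(0:10, function(a)
    exp(lchoose(10, a) + lchoose(10, k - a) - lchoose(20, k)), numeric(1))
  p_obs <- probs[2]  # a = 1
  p_oracle <- sum(probs[probs <= p_obs + 1e-12])
  expect_equal(fish$p.value, p_oracle, tolerance = 1e-9)

  ## low expected counts force Fisher even beyond 2x2
  low <- compare_datasets(c(1, 2, 1), c(2, 1, 2))
  expect_equal(low$test, "fisher")

  ## goodness-of-fit form against expected fractions
  gof <- compare_datasets(c(25, 25, 25, 25), rep(0.25, 4))
  expect_equal(gof$test, "chi-square-gof")
  expect_equal(gof$statistic, 0)

  ## Mann-Whitney on identical samples sits at its null mean
  mw <- compare_datasets(c(3, 4, 5, 6), c(3, 4, 5, 6), type = "sizes")
  expect_equal(mw$test, "mann-whitney")
  expect_equal(mw$statistic, 4 * 4 / 2)

  expect_error(compare_datasets(c(0, 0), c(1, 2)), "zero-total")
})

test_that("statistics are invariant to lineage order", {
  x <- mixed_fixture()
  xr <- x[rev(seq_len(nrow(x))), ]
  expect_equal(laminar_fractions(xr), laminar_fractions(x))
  expect_equal(class_fractions(xr), class_fractions(x))
  expect_equal(config_frequencies(xr), config_frequencies(x))
  expect_equal(size_histogram(xr), size_histogram(x))
  expect_equal(superficial_deep_correlation(xr),
               superficial_deep_correlation(x))
})
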