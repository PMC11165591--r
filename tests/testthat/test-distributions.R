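# distributions: weighted binning, combination, quantiles, W1, ranking,
# stratification

test_that("equal-precursor weighting makes total mass = distinct precursors", {
  sc <- c(0.9, 0.91, 0.92, 0.8)
  ids <- c("A/2", "A/2", "A/2", "B/1")
  d <- build_distribution(sc, ids)
  expect_equal(d$total_mass, 2)
  # literal multiplicative reading behind the flag
  d2 <- build_distribution(sc, ids, weighting = "psm_count")
  expect_equal(d2$total_mass, 3 * 3 + 1)
  # all scores in one bin
  d3 <- build_distribution(rep(0.9995, 5), paste0("P", 1:5, "/2"))
  expect_equal(sum(d3$weights > 0), 1L)
  expect_equal(d3$weights[1000], 5)
  expect_error(build_distribution(1.2, "A/2"), "outside")
})

test_that("weighted histogram equals a naive loop accumulation", {
  set.seed(31)
  sc <- round(runif(1000), 4)
  ids <- paste0("P", sample(1:300, 1000, replace = TRUE), "/2")
  d <- build_distribution(sc, ids)
  expect_equal(d$weights, oracle_hist(sc, ids, 0, 1, 0.001),
               tolerance = 1e-12)
  expect_equal(d$total_mass, length(unique(ids)))
})

test_that("combine adds bins and is associative and commutative", {
  set.seed(37)
  ds <- replicate(3, rand_dist(), simplify = FALSE)
  expect_equal(combine_distributions(ds[[1]], ds[[2]])$total_mass,
               ds[[1]]$total_mass + ds[[2]]$total_mass)
  abc <- combine_distributions(combine_distributions(ds[[1]], ds[[2]]),
                               ds[[3]])
  bca <- combine_distributions(ds[[2]],
                               combine_distributions(ds[[3]], ds[[1]]))
  expect_equal(abc$weights, bca$weights, tolerance = 1e-12)
  # identity under an all-zero distribution
  expect_equal(combine_distributions(ds[[1]], sim_dist_empty())$weights,
               ds[[1]]$weights)
  wrong <- sim_dist_empty(lo = -1)
  expect_error(combine_distributions(ds[[1]], wrong), "mismatched binning")
})

test_that("quantiles follow the bin-center crossing convention", {
  d <- build_distribution(0.8003, "A/2")  # point mass in [0.800, 0.801)
  q <- dist_quantiles(d)
  expect_true(all(q == 0.8005))
  # equal mass in two bins: median = lower bin center under crossing
  d2 <- build_distribution(c(0.1, 0.9), c("A/2", "B/2"))
  expect_equal(dist_quantiles(d2)[["median"]], 0.1005)
  expect_error(dist_quantiles(sim_dist_empty()), "empty")
})

test_that("binned quantiles track sort-based quantiles within one bin", {
  set.seed(43)
  sc <- rbeta(10000, 8, 2)
  ids <- paste0("P", seq_along(sc), "/2")  # all multiplicity 1
  d <- build_distribution(sc, ids)
  q <- dist_quantiles(d)
  # independent oracle: order statistics on the raw scores
  exact <- quantile(sc, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 1)
  expect_true(all(abs(q - exact) <= 0.001 + 1e-12))
  expect_true(all(diff(q) >= 0))
})

test_that("W1 is zero on identical input and |a-b| on point masses", {
  d1 <- build_distribution(c(0.8003, 0.9), c("A/2", "B/2"))
  expect_equal(wasserstein_distance(d1, d1), 0)
  pa <- build_distribution(0.8005, "A/2")
  pb <- build_distribution(0.9005, "A/2")
  expect_equal(wasserstein_distance(pa, pb), 0.1, tolerance = 0.001)
  expect_error(wasserstein_distance(pa, sim_dist_empty()), "empty")
  expect_error(wasserstein_distance(pa, sim_dist_empty(lo = -1)),
               "mismatched binning")
})

test_that("W1 satisfies the metric axioms on random triples", {
  set.seed(47)
  for (i in 1:20) {
    ds <- replicate(3, rand_dist(), simplify = FALSE)
    w12 <- wasserstein_distance(ds[[1]], ds[[2]])
    w21 <- wasserstein_distance(ds[[2]], ds[[1]])
    w13 <- wasserstein_distance(ds[[1]], ds[[3]])
    w23 <- wasserstein_distance(ds[[2]], ds[[3]])
    expect_equal(w12, w21, tolerance = 1e-9)
    expect_true(w13 <= w12 + w23 + 1e-9)
    expect_true(w12 >= 0)
  }
})

test_that("if W1 = 0 the quantiles agree within a bin width", {
  set.seed(53)
  d <- rand_dist()
  d2 <- d; d2$weights <- d$weights * 7; d2$total_mass <- sum(d2$weights)
  expect_equal(wasserstein_distance(d, d2), 0)
  expect_true(all(abs(dist_quantiles(d) - dist_quantiles(d2)) <= 0.001))
})

test_that("binned W1 of uniform vs shifted uniform approaches the shift", {
  set.seed(59)
  s <- 0.05
  x <- runif(1e5, 0.2, 0.7)
  d1 <- build_distribution(x, paste0("a", seq_along(x)))
  d2 <- build_distribution(x + s, paste0("b", seq_along(x)))
  expect_lt(abs(wasserstein_distance(d1, d2) - s), 3 * 0.001)
})

test_that("methods are ranked by descending median with documented ties", {
  mk <- function(center) build_distribution(center, "A/2")
  rep1 <- rank_methods(list(M1 = mk(0.9), M2 = mk(0.8), M3 = mk(0.85)))
  expect_equal(rep1$method, c("M1", "M3", "M2"))
  expect_equal(rep1$rank, 1:3)
  expect_false(any(rep1$tied))
  # tie on median -> larger q75 first, then name; flagged
  t1 <- build_distribution(c(0.8, 0.9), c("A/2", "B/2"))
  t2 <- build_distribution(c(0.8, 0.95), c("A/2", "B/2"))
  rep2 <- rank_methods(list(zeta = t1, beta = t2))
  expect_equal(rep2$method, c("beta", "zeta"))
  expect_true(all(rep2$tied))
  single <- rank_methods(list(only = mk(0.7)))
  expect_equal(single$rank, 1L)
  # W1 column appears when an experimental reference is supplied
  with_exp <- rank_methods(list(M1 = mk(0.9)), experimental = mk(0.95))
  expect_true(abs(with_exp$w1_to_experimental - 0.05) <= 0.0011)
})

test_that("strata are disjoint, exhaustive, and reweighted within stratum", {
  scored <- data.frame(
    score = c(0.9, 0.8, 0.85, 0.7),
    precursor = c("A/1", "B/2", "B/2", "C/3"),
    charge = c(1L, 2L, 2L, 3L),
    pep_n = c(8L, 12L, 12L, 29L),
    nce = c(27, 27, 27, 30),
    oxidized = c(FALSE, TRUE, TRUE, FALSE))
  by_z <- stratify_scores(scored, "charge")
  expect_length(by_z, 3L)
  expect_equal(sum(vapply(by_z, `[[`, numeric(1), "total_mass")), 3)
  by_ptm <- stratify_scores(scored, "ptm_status")
  expect_setequal(names(by_ptm), c("modified", "unmodified"))
  expect_equal(by_ptm$modified$total_mass, 1)  # one precursor, two PSMs
  by_len <- stratify_scores(scored, "length_bins")
  expect_setequal(names(by_len), c("7-10", "11-14", "27-30"))
  by_nce <- stratify_scores(scored, "nce")
  expect_length(by_nce, 2L)
  expect_error(stratify_scores(scored, "instrument"), "unknown stratifier")
})
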