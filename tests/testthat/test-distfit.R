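test_that("threshold binning closes bins at the occupancy threshold", {
  d <- tibble::tibble(degree = 1:3, count = c(50L, 30L, 20L))
  b <- threshold_bin(d, 10)
  expect_equal(b$k_min, 1:3)
  expect_equal(b$k_max, 1:3)
  expect_equal(b$count, c(50, 30, 20))

  d2 <- tibble::tibble(degree = 1:3, count = c(5L, 4L, 8L))
  b2 <- threshold_bin(d2, 9)
  expect_equal(b2$k_min, c(1L, 3L))
  expect_equal(b2$k_max, c(2L, 3L))
  expect_equal(b2$count, c(9, 8)) # last bin may fall short

  b3 <- threshold_bin(d2, 1)
  expect_equal(nrow(b3), 3) # identity binning

  # conservation and frequency normalization
  expect_equal(sum(b2$count), sum(d2$count))
  expect_equal(b2$freq, b2$count / (17 * (b2$k_max - b2$k_min + 1)))
  expect_error(threshold_bin(tibble::tibble(degree = integer(),
                                            count = integer()), 5),
               "empty")
})

test_that("rebinning onto a common grid conserves counts", {
  target <- tibble::tibble(degree = c(1L, 2L, 3L, 8L),
                           count = c(12L, 9L, 4L, 2L))
  bins <- threshold_bin(target, 10)
  other <- tibble::tibble(degree = c(0L, 2L, 15L), count = c(5L, 5L, 5L))
  re <- bin_on_grid(other, bins)
  expect_equal(re$k_min, bins$k_min)
  # out-of-range counts are dropped but depress in-grid frequencies
  expect_equal(sum(re$count), 5)
  expect_equal(re$freq, re$count / (15 * (re$k_max - re$k_min + 1)))
  expect_equal(rms_distance(bin_on_grid(target, bins), bins), 0)
})

test_that("RMS distance is a pseudometric on common-grid frequencies", {
  mk <- function(freq) {
    out <- tibble::tibble(k_min = seq_along(freq), k_max = seq_along(freq),
                          count = freq, freq = freq)
    class(out) <- c("binned_dist", class(out))
    out
  }
  a <- mk(c(0.5, 0.3, 0.2))
  b <- mk(c(0.4, 0.4, 0.2))
  expect_equal(rms_distance(a, a), 0)
  expect_equal(rms_distance(a, b), sqrt(0.02 / 3))
  expect_equal(rms_distance(a, b), rms_distance(b, a))
  expect_equal(rms_distance(mk(c(0.1, 0.1, 0.1)), mk(c(0.3, 0.3, 0.3))),
               0.2)
  set.seed(61)
  for (i in 1:20) {
    x <- mk(runif(4))
    y <- mk(runif(4))
    z <- mk(runif(4))
    expect_lte(rms_distance(x, z),
               rms_distance(x, y) + rms_distance(y, z) + 1e-12)
  }
  expect_error(rms_distance(a, mk(c(0.5, 0.5))), "grids")
})

test_that("rank-sum comparison matches an exhaustive permutation oracle", {
  expect_gt(rank_sum_compare(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0.95)
  expect_lt(rank_sum_compare(rep(1, 4), rep(100, 4)), 0.05)
  set.seed(62)
  for (i in 1:10) {
    nx <- sample(3:8, 1)
    ny <- sample(3:8, 1)
    vals <- sample(1000, nx + ny) / 7 # untied
    x <- vals[seq_len(nx)]
    y <- vals[-seq_len(nx)]
    expect_equal(rank_sum_compare(x, y), permutation_rank_sum_p(x, y),
                 tolerance = 1e-9)
  }
  expect_error(rank_sum_compare(numeric(0), 1:3), "non-empty")
})

test_that("simulated targets are deterministic and well-formed", {
  pars <- growth_params(0.5, 0.5, 0.2)
  t1 <- simulate_degree_target(pars, 200, replicates = 5, seed = 63)
  t2 <- simulate_degree_target(pars, 200, replicates = 5, seed = 63)
  expect_identical(t1, t2)
  expect_equal(sum(t1$count), 5 * 200)
})

test_that("the Monte-Carlo fit is reproducible and improves its objective", {
  pars <- growth_params(0.5, 1, 0.2, q = 0.8)
  target <- simulate_degree_target(pars, 100, replicates = 5, seed = 64)
  f1 <- monte_carlo_fit(target, 100, trials = 15, replicates = 4,
                        restarts = 1, seed = 65)
  f2 <- monte_carlo_fit(target, 100, trials = 15, replicates = 4,
                        restarts = 1, seed = 65)
  expect_identical(f1$par, f2$par)
  expect_gte(f1$objective, 0)
  # best-so-far trajectory is non-increasing
  expect_true(all(diff(f1$history$best) <= 1e-15))
  expect_equal(f1$par[["p_e"]], 1)
  expect_s3_class(tidy(f1), "tbl_df")
  expect_s3_class(glance(f1), "tbl_df")
  expect_s3_class(autoplot(f1), "ggplot")
})

test_that("a degenerate edgeless target drives the edge rate to zero", {
  target <- tibble::tibble(degree = 0L, count = 100L)
  fit <- monte_carlo_fit(target, 100, trials = 80, replicates = 3,
                         restarts = 2, seed = 66)
  refit_mean_degree <- mean(fit$refit_degrees)
  expect_lt(refit_mean_degree, 0.5)
  expect_lt(fit$objective, 0.05)
})

test_that("the objective separates the two biological parameter regimes", {
  yeast_like <- growth_params(0.7, 1, 0.75, q = 0.91)
  worm_like <- growth_params(0.008, 1, 0.028, p = 0.71, q = 0.06)
  score <- function(target_bins, pars) {
    degs <- unlist(lapply(1:5, function(i) {
      igraph::degree(grow_network(pars, max_nodes = 300,
                                  seed = 7000 + i))
    }))
    rms_distance(bin_on_grid(degree_counts(degs), target_bins),
                 target_bins)
  }
  heavy <- threshold_bin(
    simulate_degree_target(yeast_like, 300, replicates = 5, seed = 67), 10)
  expect_lt(score(heavy, yeast_like), score(heavy, worm_like))
  poissonish <- threshold_bin(
    simulate_degree_target(worm_like, 300, replicates = 5, seed = 68), 10)
  expect_lt(score(poissonish, worm_like), score(poissonish, yeast_like))
})
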