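test_that("Newman modularity matches hand-computed and brute-force values", {
  tt <- two_triangles()
  mm <- rep(0:1, each = 3)
  expect_equal(newman_modularity(tt, mm), 0.5)
  expect_equal(newman_modularity(tt, rep(0L, 6)), 0)

  set.seed(31)
  for (i in 1:20) {
    g <- random_colored_graph(25, 0.15, 3)
    if (igraph::ecount(g) < 1) next
    mm <- igraph::vertex_attr(g, "color")
    qn <- newman_modularity(g)
    expect_equal(qn, brute_force_qn(g, mm), tolerance = 1e-12)
    # independent cross-check against igraph's implementation
    expect_equal(qn, igraph::modularity(g, mm + 1), tolerance = 1e-12)
    expect_lte(qn, 1)
  }
})

test_that("random module shuffles average to zero modularity", {
  g <- grow_network(growth_params(0.4, 0.8), max_nodes = 60, seed = 32)
  mm <- rep(0:1, length.out = igraph::vcount(g))
  set.seed(33)
  vals <- vapply(1:1000, function(i) {
    newman_modularity(g, sample(mm))
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.02)
  expect_gt(max(abs(vals)), 0) # individual shuffles need not vanish
})

test_that("Newman assortativity follows its mixing-matrix formula", {
  expect_equal(newman_assortativity(diag(4) / 4), 1)
  expect_equal(newman_assortativity(matrix(c(0, 0.5, 0.5, 0), 2)), -1)
  expect_error(newman_assortativity(matrix(c(1, 0, 0, 0), 2)), "undefined")
  for (nc in c(2, 4, 8, 16)) {
    for (pi in seq(0, 1, by = 0.1)) {
      e <- equal_opportunity(nc, pi)
      expected <- (nc * pi - 1) / (nc - 1)
      expect_equal(newman_assortativity(e), expected, tolerance = 1e-12)
      # identical to the trace form of the functional modularity
      expect_equal((nc * sum(diag(e)) - 1) / (nc - 1), expected,
                   tolerance = 1e-12)
    }
  }
})

test_that("functional modularity trace and sum forms agree exactly", {
  set.seed(34)
  for (i in 1:200) {
    nc <- sample(2:6, 1)
    g <- random_colored_graph(20, 0.2, nc)
    if (igraph::ecount(g) < 1) next
    qh_trace <- functional_modularity(g, method = "trace")
    qh_sum <- functional_modularity(g, method = "sum")
    expect_equal(qh_trace, qh_sum, tolerance = 1e-12)
    expect_equal(qh_sum,
                 brute_force_qh(g, igraph::vertex_attr(g, "color"), nc),
                 tolerance = 1e-12)
    expect_lte(qh_trace, 1)
    expect_gte(qh_trace, -1)
  }
})

test_that("bipartite graphs are maximally anti-modular", {
  kb <- igraph::make_full_bipartite_graph(5, 5)
  mm <- as.integer(igraph::vertex_attr(kb, "type"))
  expect_equal(functional_modularity(kb, membership = mm), -1)
  expect_equal(functional_modularity(kb, membership = mm, method = "sum"),
               -1)
  expect_error(functional_modularity(triangle(), membership = rep(0L, 3)),
               "single module")
})

test_that("the two-hub construction behaves as designed", {
  th1 <- two_hub_graph(1)
  expect_equal(igraph::vcount(th1$graph), 4)
  expect_true(igraph::isomorphic(th1$graph, path_graph(4)))

  th <- two_hub_graph(3)
  expect_equal(sort(igraph::degree(th$graph), decreasing = TRUE),
               c(4, 4, 1, 1, 1, 1, 1, 1))
  expect_equal(igraph::ecount(th$graph), 7)
  expect_equal(functional_modularity(th$graph), 5 / 7)
  # closed form (2k - 1) / (2k + 1) against the literal sum
  for (k in c(1, 2, 10, 50)) {
    g <- two_hub_graph(k)$graph
    expect_equal(functional_modularity(g, method = "sum"),
                 (2 * k - 1) / (2 * k + 1), tolerance = 1e-12)
  }
})

test_that("modularity is highest without fusion (decreasing in 1 - r)", {
  set.seed(35)
  res <- vapply(c(1, 0.75, 0.5), function(r) {
    pars <- growth_params(0.5, 1, 0.2, r = r, n_colors = 5,
                          e_matrix = equal_opportunity(5, 0.8))
    vals <- vapply(1:50, function(i) {
      g <- grow_network(pars, max_nodes = 1000,
                        initial = "one_per_module")
      c(newman_modularity(g), functional_modularity(g))
    }, numeric(2))
    rowMeans(vals)
  }, numeric(2))
  # columns ordered r = 1, 0.75, 0.5: both measures non-increasing
  expect_true(all(diff(res[1, ]) <= 0))
  expect_true(all(diff(res[2, ]) <= 0))
})

test_that("modularity-vs-pi curves reproduce the measure ordering", {
  mc <- modularity_pi_curve(c(0, 0.5, 1), n_colors = c(2L, 16L),
                            n_nodes = 400, replicates = 15, seed = 36)
  at <- function(pi, nc, col) mc[[col]][mc$pi == pi & mc$n_colors == nc]
  expect_equal(at(1, 2, "q_h"), 1)
  expect_equal(at(0, 2, "q_h"), -1)
  # Q_H > Q_N for modular, Q_H < Q_N for anti-modular networks
  expect_gt(at(1, 2, "q_h"), at(1, 2, "q_n"))
  expect_lt(at(0, 2, "q_h"), at(0, 2, "q_n"))
  # the two measures approach each other as the module count grows
  # (compared at the extremes, where the gap is well resolved)
  for (pi in c(0, 1)) {
    expect_lt(abs(at(pi, 16, "q_h") - at(pi, 16, "q_n")),
              abs(at(pi, 2, "q_h") - at(pi, 2, "q_n")))
  }
  expect_s3_class(autoplot(mc), "ggplot")
})
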