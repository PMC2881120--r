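test_that("node-only growth yields isolated nodes and replay is exact", {
  g <- grow_network(growth_params(p_n = 1, p_e = 0), max_nodes = 100,
                    seed = 1)
  expect_equal(igraph::vcount(g), 100)
  expect_equal(igraph::ecount(g), 0)

  pars <- growth_params(0.3, 0.6, 0.2, p = 0.9, q = 0.8, r = 0.7)
  ga <- grow_network(pars, max_nodes = 300, seed = 5, trace = TRUE)
  gb <- grow_network(pars, max_nodes = 300, seed = 5, trace = TRUE)
  expect_identical(igraph::as_edgelist(ga), igraph::as_edgelist(gb))
  expect_identical(igraph::vertex_attr(ga, "id"),
                   igraph::vertex_attr(gb, "id"))
  expect_identical(attr(ga, "trace"), attr(gb, "trace"))
})

test_that("unreachable stop criteria abort with a diagnostic", {
  # parameters that only shrink: node events always remove
  pars <- growth_params(p_n = 0.5, p_e = 0, p = 0)
  expect_error(grow_network(pars, max_nodes = 10, iteration_cap = 1000),
               "not reached")
})

test_that("duplication copies the neighbourhood but not the ancestor", {
  # duplicate the hub of a 4-leaf star: two degree-4 hubs, leaves degree 2
  g <- duplicate_node(star4(), node = 1)
  expect_equal(igraph::ecount(g), 8)
  expect_equal(sort(igraph::degree(g), decreasing = TRUE),
               c(4, 4, 2, 2, 2, 2))
  expect_false(igraph::are_adjacent(g, 1, 6))

  iso <- as_colored_graph(igraph::make_empty_graph(1, directed = FALSE),
                          colors = 0L)
  g2 <- duplicate_node(iso, node = 1)
  expect_equal(igraph::vcount(g2), 2)
  expect_equal(igraph::ecount(g2), 0)

  # repeated duplication from a single node can never create an edge
  pars <- growth_params(p_n = 0, p_e = 0, p_d = 1, r = 1)
  g3 <- grow_network(pars, max_nodes = 64, seed = 3)
  expect_equal(igraph::ecount(g3), 0)
})

test_that("fusion unites neighbourhoods and discards self and duplicate edges", {
  edge <- igraph::make_graph(c(1, 2), directed = FALSE)
  g <- fuse_nodes(edge, a = 1, b = 2)
  expect_equal(igraph::vcount(g), 1)
  expect_equal(igraph::ecount(g), 0)

  # fusing the two hubs of the two-hub graph: one degree-6 node
  th <- two_hub_graph(3)$graph
  g2 <- fuse_nodes(th, a = 1, b = 2)
  expect_equal(igraph::vcount(g2), 7)
  expect_equal(sort(igraph::degree(g2), decreasing = TRUE),
               c(6, 1, 1, 1, 1, 1, 1))

  # fusing nodes of two disjoint components merges them
  g3 <- fuse_nodes(two_triangles(), a = 1, b = 4)
  expect_equal(igraph::components(g3)$no, 1)
})

test_that("edge randomization keeps node count fixed and edge count stable", {
  # the add/remove balance q(1 - xi) - (1 - q)xi vanishes at xi = q, so
  # the walk in edge-number space is unbiased at density 1/2; elsewhere
  # the edge count relaxes toward that equilibrium density
  n <- 32
  m0 <- n * (n - 1) / 4
  g0 <- igraph::sample_gnm(n, m0)
  set.seed(8)
  m_after <- vapply(1:100, function(i) {
    igraph::ecount(randomize_edges(g0, updates = 10 * m0))
  }, numeric(1))
  expect_equal(igraph::vcount(randomize_edges(g0, updates = 100, seed = 1)),
               n)
  expect_lt(abs(mean(m_after) - m0) / m0, 0.1)

  # a sparse graph drifts upward toward the q = 1/2 equilibrium
  sparse <- igraph::sample_gnm(40, 60)
  m_sparse <- mean(vapply(1:20, function(i) {
    igraph::ecount(randomize_edges(sparse, updates = 600))
  }, numeric(1)))
  expect_gt(m_sparse, 100)
})

test_that("asymptotic mean degree follows <k> = 2 q eta", {
  expect_equal(expected_mean_degree(growth_params(0.2, 0.2)), 2)
  expect_equal(expected_mean_degree(growth_params(0.2, 0.75)), 7.5)
  expect_equal(expected_mean_degree(growth_params(0.5, 0)), 0)
  expect_error(expected_mean_degree(growth_params(0, 1)), "node addition")
  expect_error(expected_mean_degree(growth_params(0.5, 1, p_d = 0.2)),
               "duplication")

  set.seed(12)
  kbar <- mean(vapply(1:20, function(i) {
    mean_degree(grow_network(growth_params(0.2, 0.75), max_nodes = 1000))
  }, numeric(1)))
  expect_lt(abs(kbar - 7.5) / 7.5, 0.05)
})

test_that("duplication-free growth matches the exponential closed form", {
  # grown to n = 10,000 the degree distribution sits on the geometric
  # law p(k) = (2 eta)^k / (1 + 2 eta)^(k+1)
  set.seed(13)
  ks <- vapply(1:100, function(i) {
    g <- grow_network(growth_params(0.2, 0.2), max_nodes = 10000)
    d <- igraph::degree(g)
    kmax <- max(d)
    emp <- cumsum(tabulate(d + 1, kmax + 1)) / length(d)
    theo <- cumsum(callaway_pmf(0:kmax, 1))
    max(abs(emp - theo))
  }, numeric(1))
  expect_lt(mean(ks), 0.05)
  expect_equal(sum(callaway_pmf(0:500, 3.75)), 1, tolerance = 1e-10)
  expect_equal(sum(0:500 * callaway_pmf(0:500, 3.75)), 7.5,
               tolerance = 1e-6)
})

test_that("jointly rescaled probabilities only rescale time", {
  set.seed(14)
  deg_full <- unlist(lapply(1:30, function(i) {
    igraph::degree(grow_network(growth_params(0.4, 0.8, 0.2),
                                max_iterations = 1000))
  }))
  deg_half <- unlist(lapply(1:30, function(i) {
    igraph::degree(grow_network(growth_params(0.2, 0.4, 0.1),
                                max_iterations = 2000))
  }))
  expect_gt(rank_sum_compare(deg_full, deg_half), 0.01)
})

test_that("duplication fattens the degree-distribution tail monotonically", {
  set.seed(15)
  q99 <- vapply(c(0, 0.25, 0.5), function(pd) {
    mean(vapply(1:50, function(i) {
      g <- grow_network(growth_params(0.2, 0.75, pd), max_nodes = 1000)
      unname(stats::quantile(igraph::degree(g), 0.99))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(q99) >= 0))
  expect_gt(q99[3], 1.5 * q99[1])
})

test_that("initial conditions seed the requested nodes", {
  pars <- growth_params(0.5, 0.5, n_colors = 3,
                        color_probs = c(0.2, 0.3, 0.5))
  g <- grow_network(pars, max_iterations = 0, initial = "one_per_module")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(sort(igraph::vertex_attr(g, "color")), 0:2)

  init <- two_hub_graph(2)$graph
  g2 <- grow_network(growth_params(0.5, 0.5, n_colors = 2),
                     max_iterations = 0, initial = init)
  expect_equal(igraph::ecount(g2), igraph::ecount(init))

  g3 <- grow_network(pars, max_iterations = 0)
  expect_equal(igraph::vcount(g3), 1)
  expect_equal(igraph::vertex_attr(g3, "color"), 0L)
})

test_that("the trace log replays the run's events", {
  pars <- growth_params(0.6, 0.6, 0.3, p = 0.8, q = 0.7, r = 0.5)
  g <- grow_network(pars, max_iterations = 500, seed = 21, trace = TRUE)
  tr <- attr(g, "trace")
  expect_true(all(tr$event %in% c("node_add", "node_remove", "edge_add",
                                  "edge_remove", "duplicate", "fuse")))
  # net node additions recorded in the trace match the final node count
  n_from_trace <- sum(tr$event == "node_add" & tr$success) -
    sum(tr$event == "node_remove" & tr$success) +
    sum(tr$event == "duplicate" & tr$success) -
    sum(tr$event == "fuse" & tr$success) + 1
  expect_equal(n_from_trace, igraph::vcount(g))
})
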