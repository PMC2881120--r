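# Small fixture graphs and independent brute-force oracles.

triangle <- function() igraph::make_ring(3)

path_graph <- function(n) {
  igraph::make_graph(rbind(seq_len(n - 1), 2:n), directed = FALSE)
}

star4 <- function() igraph::make_star(5, mode = "undirected", center = 1)

two_triangles <- function() {
  igraph::disjoint_union(igraph::make_ring(3), igraph::make_ring(3))
}

# ring of n nodes, each joined to neighbours within distance 2, plus a few
# random chords: the classic high-clustering / short-path construction
ring_with_shortcuts <- function(n = 100, chords = 10, seed = 1) {
  set.seed(seed)
  ring <- rbind(seq_len(n), c(2:n, 1))
  next2 <- rbind(seq_len(n), c(3:n, 1, 2))
  g <- igraph::make_graph(cbind(ring, next2), directed = FALSE)
  repeat {
    ends <- matrix(sample.int(n, 2 * chords, replace = TRUE), ncol = 2)
    ok <- ends[, 1] != ends[, 2]
    if (all(ok)) break
  }
  igraph::simplify(igraph::add_edges(g, t(ends)))
}

random_colored_graph <- function(n, p_edge, n_colors) {
  g <- igraph::sample_gnp(n, p_edge)
  as_colored_graph(g, colors = sample.int(n_colors, n, replace = TRUE) - 1L,
                   n_colors = n_colors)
}

# Literal double-sum evaluation of Newman's modularity from the dense
# adjacency matrix -- the oracle for the edge-list implementation.
brute_force_qn <- function(g, membership) {
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  deg <- rowSums(a)
  m <- sum(a) / 2
  s <- outer(membership, membership, "==") * 1
  sum((a - outer(deg, deg) / (2 * m)) * s) / (2 * m)
}

# Literal double-sum evaluation of the functional modularity Q_H.
brute_force_qh <- function(g, membership, n_colors) {
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  m <- sum(a) / 2
  s <- outer(membership, membership, "==") * 1
  s[s == 0] <- -1 / (n_colors - 1)
  diag(s) <- 1 # irrelevant: diag(a) = 0
  sum(a * s) / (2 * m)
}

# Exhaustive two-sided rank-sum p-value by enumerating every assignment
# of the pooled values to the two groups (no ties assumed). Mirrors the
# doubling rule of the exact Mann-Whitney test.
permutation_rank_sum_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(pooled), nx)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}
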