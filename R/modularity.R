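resolve_membership <- function(g, membership) {
  if (is.null(membership)) {
    vertex_colors(g)
  } else {
    mm <- as.integer(round(membership))
    if (length(mm) != igraph::vcount(g)) {
      stop("`membership` must have one entry per vertex")
    }
    if (any(mm < 0)) stop("module labels must be nonnegative integers")
    mm
  }
}

#' Topological and functional modularity measures
#'
#' `newman_modularity()` computes Newman's
#' `Q_N = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) S_ij`,
#' the excess of within-module edges over the degree-preserving random
#' expectation (`S_ij = 1` when i and j share a module). Bounded above
#' by 1; can be negative; zero when everything is one module.
#'
#' `newman_assortativity()` computes `r = (Tr e - sum a_k^2) /
#' (1 - sum a_k^2)` from a mixing matrix, where `a_k` are the row sums.
#'
#' `functional_modularity()` computes `Q_H`, which drops the
#' `k_i k_j / 2m` bias and scores edges by color agreement alone:
#' an edge between like colors counts `+1`, between unlike colors
#' `-1/(n_colors - 1)` (unlike edges are penalized most heavily when
#' there are few colors), normalized by the edge count. Equivalently,
#' via the mixing matrix, `Q_H = (n_colors * Tr e - 1) / (n_colors - 1)`.
#' Both code paths are implemented (`method = "sum"` and `"trace"`) and
#' agree to machine precision. `Q_H` is 1 for perfectly modular graphs,
#' ~0 for random colorings, and -1 for bipartite (anti-modular) graphs.
#'
#' @param g A colored igraph with at least one edge.
#' @param membership Optional module labels (0-based integers), one per
#'   vertex; defaults to the graph's `color` attribute.
#' @param e A mixing matrix (symmetric, entries summing to 1), e.g. from
#'   [mixing_matrix()].
#' @param method `Q_H` code path: `"trace"` (via the mixing matrix) or
#'   `"sum"` (literal sum over edges).
#' @param n_colors Number of modules for `functional_modularity()`;
#'   defaults to the graph attribute (or `max(membership) + 1` when an
#'   explicit `membership` is supplied).
#' @return A single number.
#' @seealso [mixing_matrix()], [two_hub_graph()]
#' @export
#' @examples
#' g <- igraph::make_ring(6)
#' newman_modularity(g, membership = c(0, 0, 0, 1, 1, 1))
newman_modularity <- function(g, membership = NULL) {
  mm <- resolve_membership(g, membership)
  m <- igraph::ecount(g)
  if (m < 1) stop("modularity undefined for edgeless graph")
  deg <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  within <- sum(mm[el[, 1]] == mm[el[, 2]])
  deg_sums <- tapply(deg, mm, sum)
  within / m - sum((deg_sums / (2 * m))^2)
}

#' @rdname newman_modularity
#' @export
newman_assortativity <- function(e) {
  e <- as.matrix(e)
  if (abs(sum(e) - 1) > 1e-8) stop("mixing matrix entries must sum to 1")
  a <- rowSums(e)
  denom <- 1 - sum(a^2)
  if (denom <= 1e-12) {
    stop("assortativity undefined: all edges within one color")
  }
  (sum(diag(e)) - sum(a^2)) / denom
}

#' @rdname newman_modularity
#' @export
functional_modularity <- function(g, membership = NULL,
                                  method = c("trace", "sum"),
                                  n_colors = NULL) {
  method <- match.arg(method)
  mm <- resolve_membership(g, membership)
  if (is.null(n_colors)) {
    n_colors <- if (is.null(membership)) {
      netgrow::n_colors(g)
    } else {
      max(mm) + 1L
    }
  }
  n_colors <- as.integer(n_colors)
  if (n_colors < 2L) {
    stop("Q_H is undefined for a single module (division by n_colors - 1)")
  }
  m <- igraph::ecount(g)
  if (m < 1) stop("Q_H undefined for edgeless graph")
  el <- igraph::as_edgelist(g, names = FALSE)
  same <- mm[el[, 1]] == mm[el[, 2]]
  if (method == "sum") {
    # (1/2m) sum_ij A_ij S~_ij: each edge counted twice
    (sum(same) - sum(!same) / (n_colors - 1)) / m
  } else {
    tr_e <- sum(same) / m # Tr of the mixing matrix
    (n_colors * tr_e - 1) / (n_colors - 1)
  }
}

#' Two-hub reference graph
#'
#' Two hubs, each attached to `k` distinct leaves, joined by a single
#' hub-hub edge (`n = 2k + 2` nodes, `m = 2k + 1` edges). With each hub
#' and its own leaves as one module, `Q_H = (2k - 1) / (2k + 1)`, which
#' tends to 1 for high-degree hubs, while Newman's `Q_N` saturates well
#' below 1 -- the construction that separates the two measures.
#'
#' @param k Number of leaf edges per hub, >= 1.
#' @return A list with elements `graph` (colored igraph; hubs are
#'   vertices 1 and 2) and `membership` (0-based module labels).
#' @export
#' @examples
#' th <- two_hub_graph(3)
#' functional_modularity(th$graph) # 5/7
two_hub_graph <- function(k) {
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1")
  n <- 2L * k + 2L
  # vertices: 1 = hub A, 2 = hub B, 3..(k+2) leaves of A, rest leaves of B
  leaves_a <- 2L + seq_len(k)
  leaves_b <- 2L + k + seq_len(k)
  el <- rbind(c(1L, 2L), cbind(1L, leaves_a), cbind(2L, leaves_b))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(el))
  membership <- c(0L, 1L, rep(0L, k), rep(1L, k))
  g <- as_colored_graph(g, colors = membership, n_colors = 2L)
  list(graph = g, membership = membership)
}

#' Modularity of grown networks versus intra-module edge probability
#'
#' For each value on `pi_grid`, grows `replicates` networks with the
#' equal-opportunity e-matrix and returns replicate means of `Q_N` and
#' `Q_H`. Reproduces the characteristic ordering: `Q_H > Q_N` for
#' modular networks (large pi), `Q_H < Q_N` for anti-modular ones, with
#' the gap shrinking as the number of modules grows.
#'
#' @param pi_grid Intra-module edge probabilities to sweep.
#' @param n_colors Number of modules (may be a vector; one curve each).
#' @param params Baseline [growth_params()] whose `n_colors`,
#'   `color_probs` and `e_matrix` are replaced per grid point. The
#'   default matches the reference setup `P_N = 0.5, P_E = 1,
#'   p = q = 1, P_D = 0`.
#' @param n_nodes Target size of each grown network.
#' @param replicates Networks per grid point.
#' @param seed Optional master seed (one RNG stream for the whole sweep).
#' @return A tibble (class `modularity_curve`) with columns `pi`,
#'   `n_colors`, `q_n`, `q_h` and their standard errors.
#' @export
modularity_pi_curve <- function(pi_grid, n_colors = 2L,
                                params = growth_params(p_n = 0.5, p_e = 1),
                                n_nodes = 1000, replicates = 50,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(pi = pi_grid, n_colors = as.integer(n_colors))
  rows <- purrr::pmap(grid, function(pi, n_colors) {
    pars <- growth_params(
      p_n = params$p_n, p_e = params$p_e, p_d = params$p_d,
      p = params$p, q = params$q, r = params$r,
      n_colors = n_colors,
      e_matrix = equal_opportunity(n_colors, pi),
      edge_retries = params$edge_retries)
    vals <- vapply(seq_len(replicates), function(i) {
      g <- grow_network(pars, max_nodes = n_nodes,
                        initial = "one_per_module")
      if (igraph::ecount(g) < 1) return(c(NA_real_, NA_real_))
      c(newman_modularity(g), functional_modularity(g))
    }, numeric(2))
    tibble::tibble(
      pi = pi, n_colors = n_colors,
      q_n = mean(vals[1, ], na.rm = TRUE),
      q_h = mean(vals[2, ], na.rm = TRUE),
      q_n_se = stats::sd(vals[1, ], na.rm = TRUE) / sqrt(replicates),
      q_h_se = stats::sd(vals[2, ], na.rm = TRUE) / sqrt(replicates))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("modularity_curve", class(out))
  out
}

#' @export
autoplot.modularity_curve <- function(object, ...) {
  long <- tidyr_pivot(object)
  ggplot2::ggplot(long, ggplot2::aes(.data$pi, .data$value,
                                     colour = factor(.data$n_colors),
                                     linetype = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(pi ~ "(intra-module edge probability)"),
                  y = "modularity", colour = "modules",
                  linetype = "measure") +
    ggplot2::theme_minimal()
}

# minimal long-format helper (avoids a tidyr dependency for one call)
tidyr_pivot <- function(df) {
  dplyr::bind_rows(
    tibble::tibble(pi = df$pi, n_colors = df$n_colors,
                   measure = "Q_N", value = df$q_n),
    tibble::tibble(pi = df$pi, n_colors = df$n_colors,
                   measure = "Q_H", value = df$q_h))
}
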