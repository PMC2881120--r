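#' Component-weighted mean shortest path
#'
#' Within each connected component of size >= 2, averages the shortest
#' path over unordered node pairs; the overall value weights component
#' means by component node count. Isolated nodes carry no paths and do
#' not contribute. This convention is applied identically to grown
#' networks and their random baselines so the ratio `lambda_g` is
#' comparable below the percolation threshold.
#'
#' @param g An igraph object with at least one component of size >= 2.
#' @return Mean shortest path length.
#' @export
#' @examples
#' mean_shortest_path(igraph::make_ring(3)) # 1
mean_shortest_path <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) stop("no paths: need at least two nodes")
  comp <- igraph::components(g)
  keep <- which(comp$csize >= 2)
  if (length(keep) == 0) stop("no paths: all nodes are isolated")
  dm <- igraph::distances(g)
  w_total <- 0
  acc <- 0
  for (cc in keep) {
    idx <- which(comp$membership == cc)
    sub <- dm[idx, idx]
    l_c <- mean(sub[upper.tri(sub)])
    acc <- acc + comp$csize[cc] * l_c
    w_total <- w_total + comp$csize[cc]
  }
  acc / w_total
}

#' Triangle (transitivity) clustering coefficient
#'
#' Global clustering: three times the number of triangles over the
#' number of connected triples. This is the "triangle" coefficient, not
#' the per-node average. Returns 0 with a warning when the graph has no
#' connected triples.
#'
#' @param g An igraph object with at least three nodes.
#' @return Clustering coefficient in \[0, 1\].
#' @export
clustering_coefficient <- function(g) {
  if (igraph::vcount(g) < 3) stop("clustering needs at least three nodes")
  val <- igraph::transitivity(g, type = "global")
  if (is.nan(val)) {
    warning("no connected triples; clustering coefficient set to 0")
    val <- 0
  }
  val
}

#' Erdos-Renyi G(n, m) baseline for small-world statistics
#'
#' Samples `replicates` uniform random graphs with exactly `n` nodes and
#' `m` edges and returns the mean component-weighted shortest path and
#' the pooled triangle clustering coefficient (total triangles over
#' total triples across replicates -- per-replicate ratios are
#' 0/0-unstable for sparse graphs).
#'
#' @param n,m Node and edge counts (`m <= n(n-1)/2`).
#' @param replicates Number of G(n, m) samples (default 20).
#' @return A list with `l_random`, `c_random`, `replicates`.
#' @export
er_baseline <- function(n, m, replicates = 20) {
  if (m > n * (n - 1) / 2) stop("m exceeds the number of node pairs")
  l_vals <- numeric(replicates)
  tri <- 0
  triples <- 0
  for (i in seq_len(replicates)) {
    gr <- igraph::sample_gnm(n, m)
    l_vals[i] <- mean_shortest_path(gr)
    adj_tri <- igraph::count_triangles(gr)
    tri <- tri + sum(adj_tri) / 3
    deg <- igraph::degree(gr)
    triples <- triples + sum(deg * (deg - 1) / 2)
  }
  list(l_random = mean(l_vals),
       c_random = if (triples > 0) 3 * tri / triples else 0,
       replicates = replicates)
}

#' Small-world statistics of a graph
#'
#' Compares a graph to Erdos-Renyi G(n, m) baselines with the same node
#' and edge counts: `lambda_g = L_g / L_random`,
#' `gamma_g = C_g / C_random`, and the small-world-ness measure
#' `S_delta = gamma_g / lambda_g`. A network is non-trivially
#' small-world when `S_delta > 1` while the edge density is low
#' (`xi < 0.1`); dense networks are flagged as trivially small-world.
#'
#' @param g The graph.
#' @param replicates Baseline G(n, m) samples.
#' @param seed Optional seed for the baseline sampling.
#' @return A list of class `small_world_stats` with fields `l_g`, `c_g`,
#'   `l_random`, `c_random`, `lambda_g`, `gamma_g`, `s_delta`, `xi`,
#'   `trivially_small_world`.
#' @export
small_world_stats <- function(g, replicates = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  l_g <- mean_shortest_path(g)
  c_g <- clustering_coefficient(g)
  base <- er_baseline(n, m, replicates)
  lambda_g <- l_g / base$l_random
  gamma_g <- if (base$c_random > 0) c_g / base$c_random else NA_real_
  xi <- edge_density(g)
  out <- list(l_g = l_g, c_g = c_g,
              l_random = base$l_random, c_random = base$c_random,
              lambda_g = lambda_g, gamma_g = gamma_g,
              s_delta = gamma_g / lambda_g, xi = xi,
              trivially_small_world = xi >= 0.1)
  class(out) <- "small_world_stats"
  out
}

#' @export
print.small_world_stats <- function(x, ...) {
  cat("<small_world_stats>\n")
  cat(sprintf("  L_g = %.4g  (L_random = %.4g)  lambda_g = %.4g\n",
              x$l_g, x$l_random, x$lambda_g))
  cat(sprintf("  C_g = %.4g  (C_random = %.4g)  gamma_g  = %.4g\n",
              x$c_g, x$c_random, x$gamma_g))
  cat(sprintf("  S_delta = %.4g   xi = %.4g%s\n", x$s_delta, x$xi,
              if (isTRUE(x$trivially_small_world))
                "  [dense: trivially small-world]" else ""))
  invisible(x)
}

#' @export
glance.small_world_stats <- function(x, ...) {
  tibble::tibble(l_g = x$l_g, c_g = x$c_g, l_random = x$l_random,
                 c_random = x$c_random, lambda_g = x$lambda_g,
                 gamma_g = x$gamma_g, s_delta = x$s_delta, xi = x$xi,
                 trivially_small_world = x$trivially_small_world)
}

#' Small-world sweep over the node-to-edge event probability ratio
#'
#' For each ratio `P_N / P_E` on the grid, grows `replicates` networks
#' to `n_nodes` nodes (`P_E` fixed, `P_N = ratio * P_E`), measures the
#' component-weighted mean shortest path and pooled triangle clustering,
#' and normalizes against a G(n, m) baseline drawn at the rounded mean
#' edge count of the grown replicates. Short paths beat the baseline
#' (`lambda_g < 1`) for ratios up to about 1.5, the clustering ratio
#' peaks near 0.65, and `S_delta > 1` for ratios below about 1.3.
#'
#' @param ratio_grid Values of `P_N / P_E` to sweep.
#' @param p_e Edge-event probability held fixed (default 0.4 so ratios
#'   up to 2.5 keep `P_N <= 1`).
#' @param q,p_d,r,p Remaining growth parameters.
#' @param n_nodes Grown network size (default 200).
#' @param replicates Grown networks per grid point (default 100).
#' @param baseline_replicates G(n, m) samples per grid point.
#' @param seed Optional master seed.
#' @return A tibble (class `small_world_sweep`): `ratio`, `l_g`, `c_g`,
#'   `l_random`, `c_random`, `lambda_g`, `gamma_g`, `s_delta`, `xi`,
#'   `l_se`, `mean_m`.
#' @export
small_world_sweep <- function(ratio_grid, p_e = 0.4, q = 1, p_d = 0,
                              r = 1, p = 1, n_nodes = 200,
                              replicates = 100, baseline_replicates = 20,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(ratio_grid * p_e > 1)) {
    stop("ratio * p_e exceeds 1; lower `p_e`")
  }
  rows <- lapply(ratio_grid, function(ratio) {
    pars <- growth_params(p_n = ratio * p_e, p_e = p_e, p_d = p_d,
                          p = p, q = q, r = r)
    l_vals <- numeric(replicates)
    m_vals <- numeric(replicates)
    tri <- 0
    triples <- 0
    for (i in seq_len(replicates)) {
      g <- grow_network(pars, max_nodes = n_nodes)
      l_vals[i] <- mean_shortest_path(g)
      m_vals[i] <- igraph::ecount(g)
      adj_tri <- igraph::count_triangles(g)
      tri <- tri + sum(adj_tri) / 3
      deg <- igraph::degree(g)
      triples <- triples + sum(deg * (deg - 1) / 2)
    }
    c_g <- if (triples > 0) 3 * tri / triples else 0
    base <- er_baseline(n_nodes, round(mean(m_vals)), baseline_replicates)
    lambda_g <- mean(l_vals) / base$l_random
    gamma_g <- if (base$c_random > 0) c_g / base$c_random else NA_real_
    tibble::tibble(
      ratio = ratio, l_g = mean(l_vals), c_g = c_g,
      l_random = base$l_random, c_random = base$c_random,
      lambda_g = lambda_g, gamma_g = gamma_g,
      s_delta = gamma_g / lambda_g,
      xi = mean(m_vals) / (n_nodes * (n_nodes - 1) / 2),
      l_se = stats::sd(l_vals) / sqrt(replicates),
      mean_m = mean(m_vals))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("small_world_sweep", class(out))
  out
}

#' @export
autoplot.small_world_sweep <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(ratio = object$ratio, measure = "lambda_g",
                   value = object$lambda_g),
    tibble::tibble(ratio = object$ratio, measure = "gamma_g",
                   value = object$gamma_g),
    tibble::tibble(ratio = object$ratio, measure = "S_delta",
                   value = object$s_delta))
  ggplot2::ggplot(long, ggplot2::aes(.data$ratio, .data$value,
                                     colour = .data$measure)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(P[N] / P[E]), y = NULL) +
    ggplot2::theme_minimal()
}

#' Percolation sweep: giant component versus the edge-to-node ratio
#'
#' For each ratio `P_E / P_N` (and each value of `p_n` supplied), grows
#' `replicates` networks to the stop criterion and averages the relative
#' size of the largest connected component. Curves for different
#' absolute `p_n` at matched ratios coincide within sampling error: the
#' percolation transition depends on the event probabilities only
#' through their ratio. Fusion (`p_d > 0`, `r = 0`) shifts the onset to
#' smaller ratios because fusing nodes of different clusters merges
#' whole clusters.
#'
#' @param ratio_grid Values of `P_E / P_N`.
#' @param p_n Node-event probability; may be a vector (one curve each).
#' @param p_d,r,p,q Remaining growth parameters.
#' @param max_nodes,max_edges Stop criterion (exactly one).
#' @param replicates Networks per grid point (default 100).
#' @param seed Optional master seed.
#' @return A tibble (class `percolation_sweep`): `ratio`, `p_n`, `p_d`,
#'   `s_mean`, `s_se`, `replicates`.
#' @export
percolation_sweep <- function(ratio_grid, p_n = 1, p_d = 0, r = 1,
                              p = 1, q = 1, max_nodes = 100,
                              max_edges = NULL, replicates = 100,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(max_edges)) max_nodes <- NULL
  grid <- expand.grid(ratio = ratio_grid, p_n = p_n)
  feasible <- grid$ratio * grid$p_n <= 1
  if (!any(feasible)) stop("ratio * p_n exceeds 1 everywhere; lower `p_n`")
  if (!all(feasible)) {
    warning(sum(!feasible), " ratio/p_n combinations need P_E > 1; dropped")
    grid <- grid[feasible, ]
  }
  rows <- purrr::pmap(grid, function(ratio, p_n) {
    pars <- growth_params(p_n = p_n, p_e = ratio * p_n, p_d = p_d,
                          p = p, q = q, r = r)
    s_vals <- vapply(seq_len(replicates), function(i) {
      g <- grow_network(pars, max_nodes = max_nodes,
                        max_edges = max_edges)
      giant_component_fraction(g)
    }, numeric(1))
    tibble::tibble(ratio = ratio, p_n = p_n, p_d = p_d,
                   s_mean = mean(s_vals),
                   s_se = stats::sd(s_vals) / sqrt(replicates),
                   replicates = replicates)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("percolation_sweep", class(out))
  out
}

#' @export
autoplot.percolation_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$ratio, .data$s_mean,
                               colour = interaction(.data$p_n, .data$p_d,
                                                    sep = " / "))) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$s_mean - .data$s_se,
      ymax = .data$s_mean + .data$s_se), size = 0.2) +
    ggplot2::labs(x = expression(P[E] / P[N]), y = "giant component S",
                  colour = expression(P[N] / P[D])) +
    ggplot2::theme_minimal()
}

#' Curve summaries used for figure-level readouts
#'
#' `threshold_crossing()` linearly interpolates the x position where a
#' curve first crosses `level` (scanning left to right);
#' `smoothed_argmax()` fits a loess smoother and returns the x of its
#' maximum on a fine grid.
#'
#' @param x,y Curve coordinates (x ascending).
#' @param level Crossing level.
#' @param span Loess span (default 0.5).
#' @return A single x value (`NA` if the curve never crosses).
#' @export
threshold_crossing <- function(x, y, level = 1) {
  stopifnot(length(x) == length(y), !is.unsorted(x))
  above <- y >= level
  i <- which(above[-1] != above[-length(above)])
  if (length(i) == 0) return(NA_real_)
  i <- i[1]
  x[i] + (level - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
}

#' @rdname threshold_crossing
#' @export
smoothed_argmax <- function(x, y, span = 0.5) {
  ok <- is.finite(y)
  df <- data.frame(x = x[ok], y = y[ok])
  fit <- stats::loess(y ~ x, data = df, span = span, degree = 2)
  grid <- seq(min(df$x), max(df$x), length.out = 401)
  pred <- stats::predict(fit, newdata = data.frame(x = grid))
  grid[which.max(pred)]
}
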