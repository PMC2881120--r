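#' Growth-model parameters
#'
#' Bundles the six event probabilities of the stochastic growth model
#' with the module structure. Per iteration, three sub-events fire
#' independently and are handled sequentially (node, then edge, then
#' duplication):
#' \describe{
#'   \item{`p_n`}{node-event probability; given a node event, a node is
#'     added with probability `p` (without edges, color drawn from
#'     `color_probs`), else a uniformly random node and its incident
#'     edges are removed.}
#'   \item{`p_e`}{edge-event probability; given an edge event, an
#'     addition is attempted with probability `q` (a uniformly random
#'     pair is connected only if currently unconnected), else a removal
#'     is attempted (carried out only if the random pair is connected).}
#'   \item{`p_d`}{duplication-event probability; given one, a uniformly
#'     random node is duplicated with probability `r` (the copy keeps
#'     the ancestor's color and neighbours, with no ancestor-copy edge),
#'     else two uniformly random nodes are fused (the survivor unites
#'     both neighbour sets; the selection is module independent).}
#' }
#' With an assortativity matrix `e_matrix`, edge addition draws a random
#' pair, reads the entry for their colors, and places the edge when a
#' uniform draw falls below it (and the pair is unconnected), retrying
#' up to `edge_retries` times.
#'
#' Rescaling `p_n`, `p_e`, `p_d` by a common factor only changes the
#' number of iterations needed to reach a given size, so `eta = p_e/p_n`
#' is the parameter that controls the mean degree.
#'
#' @param p_n,p_e,p_d Event probabilities in \[0, 1\].
#' @param p,q,r Conditional addition (vs removal/fusion) probabilities.
#' @param n_colors Number of modules (colors), >= 1.
#' @param color_probs Probability vector of length `n_colors` used to
#'   draw the color of each newly added node; defaults to uniform.
#' @param e_matrix Optional `n_colors` x `n_colors` symmetric matrix of
#'   color-pair connection probabilities (entries in \[0, 1\]).
#' @param edge_retries Attempt budget for e-matrix edge placement
#'   (default 1000). Without an e-matrix a single attempt is made.
#' @return An object of class `growth_params`.
#' @export
#' @examples
#' growth_params(p_n = 0.2, p_e = 0.75)
growth_params <- function(p_n, p_e, p_d = 0, p = 1, q = 1, r = 1,
                          n_colors = 1L, color_probs = NULL,
                          e_matrix = NULL, edge_retries = 1000L) {
  probs <- c(p_n = p_n, p_e = p_e, p_d = p_d, p = p, q = q, r = r)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all six probabilities must lie in [0, 1]")
  }
  n_colors <- as.integer(n_colors)
  if (n_colors < 1L) stop("`n_colors` must be >= 1")
  if (is.null(color_probs)) color_probs <- rep(1 / n_colors, n_colors)
  if (length(color_probs) != n_colors || any(color_probs < 0)) {
    stop("`color_probs` must be a nonnegative vector of length n_colors")
  }
  if (abs(sum(color_probs) - 1) > 1e-8) {
    stop("`color_probs` must sum to 1")
  }
  if (!is.null(e_matrix)) {
    e_matrix <- validate_assort_matrix(e_matrix)
    if (nrow(e_matrix) != n_colors) {
      stop("`e_matrix` dimension must equal `n_colors`")
    }
  }
  structure(
    list(p_n = p_n, p_e = p_e, p_d = p_d, p = p, q = q, r = r,
         n_colors = n_colors, color_probs = color_probs,
         e_matrix = e_matrix, edge_retries = as.integer(edge_retries)),
    class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("<growth_params>\n")
  cat(sprintf("  P_N = %g (p = %g)   P_E = %g (q = %g)   P_D = %g (r = %g)\n",
              x$p_n, x$p, x$p_e, x$q, x$p_d, x$r))
  if (x$p_n > 0) cat(sprintf("  eta = P_E/P_N = %g\n", x$p_e / x$p_n))
  cat(sprintf("  n_colors = %d%s\n", x$n_colors,
              if (is.null(x$e_matrix)) "" else " (with e-matrix)"))
  invisible(x)
}

trace_labels <- c("node_add", "node_remove", "edge_add", "edge_remove",
                  "duplicate", "fuse")

#' Grow (or shrink) a network by stochastic events
#'
#' Runs the event engine under `params` from an initial configuration
#' until the stop criterion is reached. Exactly one of `max_nodes`,
#' `max_edges`, `max_iterations` must be given. Runs are bit-identical
#' under a fixed `seed`.
#'
#' @param params A [growth_params()] object.
#' @param max_nodes Stop as soon as the node count reaches this value.
#' @param max_edges Stop as soon as the edge count reaches this value.
#' @param max_iterations Run exactly this many iterations.
#' @param initial `"seed"` (a single degree-0 node of the first module),
#'   `"one_per_module"` (one degree-0 node of each color), or an igraph
#'   to start from.
#' @param seed Optional integer; if given, `set.seed(seed)` is called.
#' @param trace If `TRUE`, attach a per-sub-event log as attribute
#'   `"trace"` (tibble: iteration, event, success, node ids).
#' @param iteration_cap Safety cap for `max_nodes`/`max_edges` runs whose
#'   target is unreachable (e.g. parameters that only shrink); the run
#'   aborts with a diagnostic once the cap is hit. Default `1e7`.
#' @return A colored igraph; vertex attribute `id` holds the engine's
#'   never-reused node ids. If the run ends empty, an empty graph is
#'   returned with a warning.
#' @export
#' @examples
#' g <- grow_network(growth_params(0.2, 0.2), max_nodes = 500, seed = 1)
#' mean_degree(g) # close to 2 * eta = 2
grow_network <- function(params, max_nodes = NULL, max_edges = NULL,
                         max_iterations = NULL,
                         initial = c("seed", "one_per_module"),
                         seed = NULL, trace = FALSE, iteration_cap = 1e7) {
  stopifnot(inherits(params, "growth_params"))
  n_stop <- sum(!is.null(max_nodes), !is.null(max_edges),
                !is.null(max_iterations))
  if (n_stop != 1) {
    stop("give exactly one of `max_nodes`, `max_edges`, `max_iterations`")
  }
  if (!is.null(seed)) set.seed(seed)

  if (igraph::is_igraph(initial)) {
    g0 <- as_colored_graph(initial)
    if (n_colors(g0) > params$n_colors) {
      stop("initial graph uses more colors than `params$n_colors`")
    }
    init_colors <- vertex_colors(g0)
    init_edges <- igraph::as_edgelist(g0, names = FALSE) - 1L
    storage.mode(init_edges) <- "integer"
  } else {
    initial <- match.arg(initial)
    init_colors <- if (initial == "seed") 0L else seq_len(params$n_colors) - 1L
    init_edges <- matrix(integer(), ncol = 2)
  }

  res <- .grow_engine(
    params$p_n, params$p_e, params$p_d, params$p, params$q, params$r,
    cumsum(params$color_probs),
    params$e_matrix,
    params$edge_retries,
    as.integer(init_colors),
    init_edges,
    if (is.null(max_nodes)) -1 else max_nodes,
    if (is.null(max_edges)) -1 else max_edges,
    if (is.null(max_iterations)) -1 else max_iterations,
    iteration_cap,
    isTRUE(trace))

  if (isTRUE(res$capped)) {
    stop(sprintf(paste0(
      "stop criterion not reached after %g iterations ",
      "(parameters may only shrink the graph); see `iteration_cap`"),
      res$iterations))
  }

  n <- length(res$ids)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(res$edges) > 0) g <- igraph::add_edges(g, t(res$edges))
  if (n > 0) {
    igraph::vertex_attr(g, "id") <- res$ids
    igraph::vertex_attr(g, "color") <- res$colors
  }
  igraph::graph_attr(g, "n_colors") <- params$n_colors
  if (n == 0) warning("run ended with an empty graph")
  if (isTRUE(trace)) {
    tr <- tibble::as_tibble(res$trace)
    tr$event <- factor(trace_labels[tr$event], levels = trace_labels)
    tr$success <- tr$success == 1L
    attr(g, "trace") <- tr
  }
  attr(g, "iterations") <- res$iterations
  g
}

#' Randomize the edges of a graph in place
#'
#' The edge-randomization control: growth with `P_N = 0, P_E = 1,
#' q = 0.5, P_D = 0` removes and places edges randomly while keeping the
#' node count fixed. The edge count performs a random walk whose drift
#' `q(1 - xi) - (1 - q) xi` vanishes at density `xi = q`; at density 1/2
#' the walk is unbiased and the edge count is conserved on average,
#' while sparser graphs slowly gain edges toward that equilibrium (keep
#' `updates` moderate when randomizing sparse graphs).
#'
#' @param g The graph to randomize.
#' @param updates Number of iterations (edge events).
#' @param seed Optional integer seed.
#' @return The randomized graph.
#' @export
randomize_edges <- function(g, updates, seed = NULL) {
  g <- as_colored_graph(g)
  params <- growth_params(p_n = 0, p_e = 1, p_d = 0, q = 0.5,
                          n_colors = n_colors(g))
  grow_network(params, max_iterations = updates, initial = g, seed = seed)
}

#' Asymptotic mean degree of the growth model
#'
#' Steady-state balance of node and edge gains/losses (no duplication):
#' node events add `(2p - 1) P_N` nodes per iteration, edge events add
#' `q P_E (1 - xi) - (1 - q) P_E xi` edges, and each node removal takes
#' `<k>` edges with it. With `xi ~ <k>/n` this gives
#' `<k> = q P_E / (P_N / 2 + P_E / n)`, i.e. `<k> -> 2 q eta` for large
#' n (independent of `p` as long as the network grows, `p > 1/2`), and
#' `<k> = 2 eta` at `q = 1`.
#'
#' @param params A [growth_params()] with `p_n > 0` and `p_d = 0`.
#' @param n Network size; `Inf` (default) gives the asymptotic value.
#' @return The predicted mean degree.
#' @export
#' @examples
#' expected_mean_degree(growth_params(0.2, 0.75)) # 2 * 3.75 = 7.5
expected_mean_degree <- function(params, n = Inf) {
  stopifnot(inherits(params, "growth_params"))
  if (params$p_n == 0) stop("no asymptotic degree without node addition")
  if (params$p_d != 0) {
    stop("the asymptotic relation is derived without duplication events")
  }
  if (params$p <= 0.5 && params$p_e > 0) {
    warning("p <= 0.5: the network does not grow; value is formal only")
  }
  params$q * params$p_e / (params$p_n / 2 + params$p_e / n)
}

#' Closed-form degree distribution of edge-per-node growth
#'
#' For growth with `p = q = 1` and no duplication the degree
#' distribution converges to the geometric (exponential) law of the
#' Callaway et al. grown random graph,
#' `p(k) = (2 eta)^k / (1 + 2 eta)^(k + 1)`, with mean `2 eta` where
#' `eta = P_E / P_N`.
#'
#' @param k Vector of degrees (nonnegative integers).
#' @param eta Edge-to-node event probability ratio.
#' @return `p(k)`.
#' @export
callaway_pmf <- function(k, eta) {
  stopifnot(eta >= 0)
  if (eta == 0) return(as.numeric(k == 0))
  # log space: (2 eta)^k overflows for deep tails
  exp(k * log(2 * eta) - (k + 1) * log1p(2 * eta))
}

#' Single duplication and fusion events
#'
#' `duplicate_node()` copies a node: the copy gets the ancestor's color
#' and an edge to each of the ancestor's neighbours, but no edge to the
#' ancestor itself (repeated duplication of an isolated node therefore
#' never creates edges). `fuse_nodes()` merges node `b` into node `a`:
#' `a` keeps its own edges and gains `b`'s (self-loops and duplicate
#' edges discarded), and `b` is deleted. Nodes are chosen uniformly at
#' random when not supplied -- fusion in particular is module
#' independent. These are the single-event building blocks of the
#' duplication/fusion channel of [grow_network()].
#'
#' @param g A colored igraph.
#' @param node,a,b Vertex indices; drawn uniformly at random if `NULL`.
#' @return The modified graph.
#' @export
#' @examples
#' star <- igraph::make_star(5, mode = "undirected")
#' igraph::ecount(duplicate_node(star, node = 1)) # hub copied: 4 -> 8
duplicate_node <- function(g, node = NULL) {
  g <- as_colored_graph(g)
  n <- igraph::vcount(g)
  if (n < 1) return(g) # nothing to duplicate
  if (is.null(node)) node <- sample.int(n, 1)
  nbrs <- as.integer(igraph::neighbors(g, node))
  g2 <- igraph::add_vertices(g, 1,
                             color = igraph::vertex_attr(g, "color", node))
  if (length(nbrs) > 0) {
    g2 <- igraph::add_edges(g2, rbind(n + 1L, nbrs))
  }
  g2
}

#' @rdname duplicate_node
#' @export
fuse_nodes <- function(g, a = NULL, b = NULL) {
  g <- as_colored_graph(g)
  n <- igraph::vcount(g)
  if (n < 2) return(g) # nothing to fuse
  if (is.null(a) || is.null(b)) {
    pick <- sample.int(n, 2)
    if (is.null(a)) a <- pick[1]
    if (is.null(b)) b <- pick[2]
  }
  if (a == b) stop("cannot fuse a node with itself")
  nbrs_b <- setdiff(as.integer(igraph::neighbors(g, b)), a)
  nbrs_a <- as.integer(igraph::neighbors(g, a))
  new <- setdiff(nbrs_b, nbrs_a)
  if (length(new) > 0) g <- igraph::add_edges(g, rbind(a, new))
  igraph::delete_vertices(g, b)
}
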