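#' Ensure a graph is a colored, simple, undirected netgrow graph
#'
#' All netgrow measures operate on undirected simple igraph objects whose
#' vertices carry an integer `color` attribute in `0:(n_colors - 1)` (the
#' functional module tag) and whose graph attribute `n_colors` records the
#' number of modules. An uncolored graph is assigned color 0 everywhere
#' with `n_colors = 1`, so every metric also runs on unlabeled graphs.
#'
#' @param g An igraph object.
#' @param colors Optional integer vector of vertex colors (0-based),
#'   recycled checks applied; overrides any existing `color` attribute.
#' @param n_colors Optional number of modules; defaults to the existing
#'   attribute or `max(color) + 1`.
#' @return The graph with `color` and `n_colors` attributes set.
#' @export
#' @examples
#' g <- as_colored_graph(igraph::make_ring(4), colors = c(0, 1, 0, 1))
#' n_colors(g)
as_colored_graph <- function(g, colors = NULL, n_colors = NULL) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::is_directed(g)) stop("directed graphs are not supported")
  if (igraph::any_loop(g) || igraph::any_multiple(g)) {
    stop("graph must be simple (no self-loops or multi-edges)")
  }
  if (is.null(colors)) {
    colors <- igraph::vertex_attr(g, "color")
    if (is.null(colors)) colors <- rep(0L, igraph::vcount(g))
  }
  colors <- as.integer(round(colors))
  if (length(colors) != igraph::vcount(g)) {
    stop("`colors` must have one entry per vertex")
  }
  if (is.null(n_colors)) {
    n_colors <- igraph::graph_attr(g, "n_colors")
    if (is.null(n_colors)) n_colors <- max(colors, 0L) + 1L
  }
  n_colors <- as.integer(n_colors)
  if (n_colors < 1L) stop("`n_colors` must be >= 1")
  if (igraph::vcount(g) > 0 && (min(colors) < 0L || max(colors) >= n_colors)) {
    stop("vertex colors must lie in [0, n_colors)")
  }
  igraph::vertex_attr(g, "color") <- colors
  igraph::graph_attr(g, "n_colors") <- n_colors
  g
}

#' @rdname as_colored_graph
#' @export
n_colors <- function(g) {
  nc <- igraph::graph_attr(g, "n_colors")
  if (is.null(nc)) {
    col <- igraph::vertex_attr(g, "color")
    nc <- if (is.null(col)) 1L else max(as.integer(col), 0L) + 1L
  }
  as.integer(nc)
}

vertex_colors <- function(g) {
  col <- igraph::vertex_attr(g, "color")
  if (is.null(col)) rep(0L, igraph::vcount(g)) else as.integer(round(col))
}

#' Degree distribution of a graph as a count table
#'
#' Tabulates the degree k against the number of nodes of that degree.
#' Normalizing `count` by the node count gives p(k), the probability that
#' a randomly chosen node has k edges. Degree-0 nodes are retained:
#' isolated nodes are first-class citizens of the growth model.
#'
#' @param x An igraph object, or an integer vector of node degrees.
#' @return A tibble with columns `degree` and `count` (only occupied
#'   degrees, ascending) and attribute `n_nodes`.
#' @export
#' @examples
#' degree_counts(two_hub_graph(3)$graph)
degree_counts <- function(x) {
  degs <- if (igraph::is_igraph(x)) igraph::degree(x) else as.integer(x)
  if (length(degs) == 0) {
    out <- tibble::tibble(degree = integer(), count = integer())
    attr(out, "n_nodes") <- 0L
    return(out)
  }
  tab <- table(degs)
  out <- tibble::tibble(
    degree = as.integer(names(tab)),
    count = as.integer(tab)
  )
  attr(out, "n_nodes") <- length(degs)
  out
}

#' Expand a degree count table back into a vector of node degrees
#'
#' @param dist A tibble with columns `degree` and `count`.
#' @return Integer vector with one entry per node.
#' @export
counts_to_degrees <- function(dist) {
  rep(as.integer(dist$degree), times = as.integer(dist$count))
}

#' Mean degree of a graph
#'
#' Returns `2 m / n`, counting isolated nodes.
#'
#' @param g An igraph object with at least one node.
#' @return A single number.
#' @export
mean_degree <- function(g) {
  n <- igraph::vcount(g)
  if (n < 1) stop("empty graph")
  2 * igraph::ecount(g) / n
}

#' Edge density (sparseness) of a graph
#'
#' The probability xi that a randomly chosen node pair is connected:
#' `m / (n (n - 1) / 2)`.
#'
#' @param g An igraph object with at least two nodes.
#' @return A single number in \[0, 1\].
#' @export
edge_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) stop("edge density needs at least two nodes")
  igraph::ecount(g) / (n * (n - 1) / 2)
}

#' Connected components as vertex-id sets, largest first
#'
#' @param g An igraph object.
#' @return A list of integer vertex-index vectors, ordered by decreasing
#'   component size.
#' @export
graph_components <- function(g) {
  if (igraph::vcount(g) == 0) return(list())
  comp <- igraph::components(g)
  parts <- unname(split(seq_len(igraph::vcount(g)), comp$membership))
  parts[order(lengths(parts), decreasing = TRUE)]
}

#' Relative size of the giant (largest connected) component
#'
#' The percolation order parameter S: size of the largest component
#' divided by the total node count.
#'
#' @param g An igraph object with at least one node.
#' @return A single number in (0, 1\].
#' @export
giant_component_fraction <- function(g) {
  n <- igraph::vcount(g)
  if (n < 1) stop("empty graph")
  max(igraph::components(g)$csize) / n
}

# ---- file IO ------------------------------------------------------------

#' Read and write graphs
#'
#' Edge lists are two-column TSV files of 0-based node indices (an
#' optional third column is ignored); GraphML and GML files carry the
#' integer `color` node attribute.
#'
#' @param path File path.
#' @param g An igraph object.
#' @param format `"graphml"` or `"gml"`.
#' @return `read_*` return a colored igraph; `write_*` return `path`
#'   invisibly.
#' @name graph_io
NULL

#' @rdname graph_io
#' @export
read_edgelist_tsv <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#")
  if (ncol(tab) < 2) stop("edge list needs two columns")
  el <- as.matrix(tab[, 1:2]) + 1L
  n <- if (nrow(el) > 0) max(el) else 0L
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(el))
  as_colored_graph(igraph::simplify(g))
}

#' @rdname graph_io
#' @export
write_edgelist_tsv <- function(g, path) {
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname graph_io
#' @export
read_colored_graph <- function(path, format = c("graphml", "gml")) {
  format <- match.arg(format)
  g <- igraph::read_graph(path, format = format)
  g <- igraph::as_undirected(g, mode = "collapse")
  as_colored_graph(igraph::simplify(g))
}

#' @rdname graph_io
#' @export
write_colored_graph <- function(g, path, format = c("graphml", "gml")) {
  format <- match.arg(format)
  g <- as_colored_graph(g)
  # "id" is reserved by the GraphML reader; store engine node ids as
  # "node_id" in files
  if ("id" %in% igraph::vertex_attr_names(g)) {
    igraph::vertex_attr(g, "node_id") <- igraph::vertex_attr(g, "id")
    g <- igraph::delete_vertex_attr(g, "id")
  }
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
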