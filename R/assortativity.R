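validate_assort_matrix <- function(e, tol = 1e-9) {
  e <- as.matrix(e)
  if (nrow(e) != ncol(e)) stop("assortativity matrix must be square")
  if (any(!is.finite(e)) || any(e < 0) || any(e > 1)) {
    stop("assortativity matrix entries must lie in [0, 1]")
  }
  if (max(abs(e - t(e))) > tol) stop("assortativity matrix must be symmetric")
  unname(e)
}

#' Generative assortativity matrices
#'
#' `equal_opportunity()` builds the e-matrix in which like colors connect
#' with probability `pi_intra` and unlike colors share the remaining
#' probability equally: diagonal `pi_intra / n_colors`, off-diagonal
#' `(1 - pi_intra) / (n_colors * (n_colors - 1))`. The `1/n_colors`
#' factor normalizes the matrix so all entries sum to 1 and
#' `Tr e = pi_intra`; `pi_intra = 1` gives perfectly modular growth,
#' `pi_intra = 0` k-partite (anti-modular) growth.
#'
#' `kpartite_matrix()` is the vanishing-diagonal special case
#' `equal_opportunity(n_colors, 0)`: grown graphs never place an edge
#' between like colors.
#'
#' `lattice_matrix()` assigns one module per lattice site and entry 1 to
#' each listed neighbor pair (symmetrized), 0 elsewhere. Growing from
#' one node per module with `P_N = 0` then enacts a percolation problem
#' with edge probability `q * P_E` on that geometry.
#'
#' Used generatively, entries are taken verbatim as acceptance
#' probabilities for a randomly drawn node pair; only ratios between
#' entries shape the mixing structure, the absolute scale rescales the
#' overall edge-placement rate.
#'
#' @param n_colors Number of modules, >= 2.
#' @param pi_intra Intra-module edge probability in \[0, 1\].
#' @param n_sites Number of lattice sites (one module each).
#' @param neighbor_pairs Two-column matrix (or list) of 0-based site
#'   pairs that are lattice neighbors.
#' @return A symmetric matrix of connection probabilities.
#' @export
#' @examples
#' equal_opportunity(4, 0.4) # diagonal 0.1, off-diagonal 0.05
#' kpartite_matrix(2)        # bipartite: [[0, .5], [.5, 0]]
equal_opportunity <- function(n_colors, pi_intra) {
  n_colors <- as.integer(n_colors)
  if (n_colors < 2L) stop("`n_colors` must be >= 2")
  if (pi_intra < 0 || pi_intra > 1) stop("`pi_intra` must lie in [0, 1]")
  off <- (1 - pi_intra) / (n_colors * (n_colors - 1))
  e <- matrix(off, n_colors, n_colors)
  diag(e) <- pi_intra / n_colors
  e
}

#' @rdname equal_opportunity
#' @export
kpartite_matrix <- function(n_colors) {
  equal_opportunity(n_colors, 0)
}

#' @rdname equal_opportunity
#' @export
lattice_matrix <- function(n_sites, neighbor_pairs) {
  n_sites <- as.integer(n_sites)
  if (n_sites < 2L) stop("`n_sites` must be >= 2")
  if (is.list(neighbor_pairs)) {
    neighbor_pairs <- do.call(rbind, lapply(neighbor_pairs, as.integer))
  }
  neighbor_pairs <- as.matrix(neighbor_pairs)
  if (ncol(neighbor_pairs) != 2) stop("`neighbor_pairs` needs two columns")
  if (any(neighbor_pairs < 0) || any(neighbor_pairs >= n_sites)) {
    stop("neighbor pair out of range")
  }
  if (any(neighbor_pairs[, 1] == neighbor_pairs[, 2])) {
    stop("a site cannot neighbor itself")
  }
  e <- matrix(0, n_sites, n_sites)
  e[neighbor_pairs + 1L] <- 1
  e[neighbor_pairs[, 2:1, drop = FALSE] + 1L] <- 1
  e
}

#' Mixing matrix of a labeled graph
#'
#' Measures the edge-fraction matrix e of a colored graph:
#' `e[k, l]` is the fraction of edges joining color k to color l.
#' Each unlike-color edge contributes half to `e[k, l]` and half to
#' `e[l, k]`; like-color edges contribute wholly to the diagonal, so the
#' matrix is symmetric and all entries sum to 1. `Tr e` is the fraction
#' of like-color edges. Colors absent from the graph keep zero
#' rows/columns, so the dimension is always `n_colors`.
#'
#' @param g A colored igraph with at least one edge.
#' @return An `n_colors` x `n_colors` matrix.
#' @export
#' @examples
#' th <- two_hub_graph(3)
#' sum(diag(mixing_matrix(th$graph))) # 6/7 of edges are within-module
mixing_matrix <- function(g) {
  g <- as_colored_graph(g)
  m <- igraph::ecount(g)
  if (m < 1) stop("mixing matrix undefined for edgeless graph")
  nc <- n_colors(g)
  col <- vertex_colors(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  ck <- factor(col[el[, 1]], levels = 0:(nc - 1))
  cl <- factor(col[el[, 2]], levels = 0:(nc - 1))
  tab <- unclass(table(ck, cl))
  unname((tab + t(tab)) / 2 / m)
}

#' Read or write an assortativity matrix as TSV
#'
#' Plain TSV, `n_colors` rows by `n_colors` columns, validated symmetric
#' within 1e-9.
#'
#' @param path File path.
#' @param e A square symmetric matrix with entries in \[0, 1\].
#' @name ematrix_io
#' @export
read_ematrix_tsv <- function(path) {
  e <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t",
                                   comment.char = "#"))
  validate_assort_matrix(e)
}

#' @rdname ematrix_io
#' @export
write_ematrix_tsv <- function(e, path) {
  e <- validate_assort_matrix(e)
  utils::write.table(e, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
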