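#' Coerce to an undirected multigraph
#'
#' Networks are stored as undirected [igraph][igraph::igraph-package] graphs
#' in which self-loops and parallel edges are permitted (the natural habitat
#' of configuration-model graphs, where a loop contributes 2 to its vertex's
#' degree). Accepts an igraph object (directions are dropped), a two-column
#' edge matrix / data frame of 1-based vertex indices or vertex names, or an
#' edge list tibble as produced by [read_weighted_edgelist()].
#'
#' @param x Object to coerce.
#' @param n_vertices Optional vertex count (to retain isolated vertices when
#'   coercing from an integer edge list).
#' @return An undirected igraph multigraph.
#' @export
as_multigraph <- function(x, n_vertices = NULL) {
  if (igraph::is_igraph(x)) {
    if (igraph::is_directed(x)) x <- igraph::as_undirected(x, mode = "each")
    return(x)
  }
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  if (!is.matrix(x) || ncol(x) < 2L) {
    abort("`x` must be an igraph object or a two-column edge matrix/data frame.")
  }
  if (is.numeric(x)) {
    storage.mode(x) <- "integer"
    nv <- max(n_vertices %||% 0L, if (nrow(x)) max(x) else 0L)
    g <- igraph::make_empty_graph(n = nv, directed = FALSE)
    igraph::add_edges(g, t(x[, 1:2, drop = FALSE]))
  } else {
    igraph::graph_from_edgelist(x[, 1:2, drop = FALSE], directed = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Largest connected component of a graph
#'
#' The giant component is the connected subgraph holding the largest share of
#' vertices; its vertex fraction is the quantity the analytic curves call S.
#'
#' @param g An igraph graph.
#' @return A list with elements `graph` (the induced subgraph of the largest
#'   component) and `fraction` (its share of all vertices of `g`).
#' @examples
#' g <- igraph::make_ring(10)
#' giant_component(g)$fraction # 1
#' @export
giant_component <- function(g) {
  g <- as_multigraph(g)
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  list(
    graph = igraph::induced_subgraph(g, keep),
    fraction = max(comp$csize) / igraph::vcount(g)
  )
}

# CSR adjacency in insertion order; loops appear twice at their vertex
graph_csr <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  # interleave endpoints so that per-vertex neighbour order follows edge
  # insertion order whichever way igraph stores an edge's endpoints
  src <- as.vector(t(el))
  dst <- as.vector(t(el[, 2:1, drop = FALSE]))
  o <- order(src) # stable sort
  deg <- tabulate(src, nbins = n)
  list(
    offsets = c(0L, cumsum(deg)),
    targets = as.integer(dst[o] - 1L),
    n = n, m = nrow(el)
  )
}

#' Read and write plain edge lists
#'
#' `write_edgelist()` writes two whitespace-separated 1-based integer columns;
#' `read_edgelist()` reads them back. GraphML files are read with
#' [igraph::read_graph()].
#'
#' @param g An igraph graph.
#' @param path File path.
#' @return `read_edgelist()` and `read_graphml()` return an igraph graph.
#' @export
write_edgelist <- function(g, path) {
  g <- as_multigraph(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  utils::write.table(el, path,
    row.names = FALSE, col.names = FALSE, sep = "\t", quote = FALSE
  )
  invisible(path)
}

#' @rdname write_edgelist
#' @param n_vertices Optional vertex count override.
#' @export
read_edgelist <- function(path, n_vertices = NULL) {
  el <- utils::read.table(path, comment.char = "#")
  as_multigraph(as.matrix(el[, 1:2]), n_vertices = n_vertices)
}

#' @rdname write_edgelist
#' @export
read_graphml <- function(path) {
  as_multigraph(igraph::read_graph(path, format = "graphml"))
}

#' Summarise a multigraph
#'
#' @param g An igraph graph.
#' @return A one-row tibble: vertex count, edge count, average degree, number
#'   of self-loops and parallel edges, and the giant-component fraction.
#' @export
graph_info <- function(g) {
  g <- as_multigraph(g)
  deg <- igraph::degree(g, loops = TRUE)
  tibble(
    n_vertices = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    avg_degree = mean(deg),
    n_loops = sum(igraph::which_loop(g)),
    n_multiple = sum(igraph::which_multiple(g)),
    gc_fraction = giant_component(g)$fraction
  )
}
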