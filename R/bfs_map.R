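#' Two-queue breadth-first-search mapping of a network
#'
#' Runs the FIFO breadth-first search that maps a network into the plane.
#' Newly touched vertices enter *QueueT* in uniformly shuffled order; each is
#' assigned the coordinates (own QueueT position / N, parent's QueueT
#' position / N), forming the BFS-tree point cloud. A second queue, *QueueG*,
#' starts with the root's own copy and then receives one copy per incident
#' edge endpoint of each explored vertex (touched or not), preserving the
#' full linking information; each copy gets the coordinates (own QueueG
#' position / N, QueueG position of the parent's *reference copy* -- the copy
#' through which the parent was first touched). The BFS-graph cloud traces
#' the network's characteristic curve.
#'
#' The root defaults to one end of a uniformly chosen edge of the giant
#' component (so the curve describes the giant component); a self-loop
#' contributes two copies and never touches a new vertex; parallel edges
#' contribute one copy per endpoint occurrence.
#'
#' @param g An igraph graph (multigraphs welcome).
#' @param root Optional 1-based root vertex id. Out-of-range ids are an error.
#' @param seed Optional integer seed (drives root choice and all shuffles).
#' @param shuffle Shuffle each explored vertex's neighbours (default). With
#'   `FALSE` neighbours are visited in edge-insertion order -- useful for
#'   replaying a prescribed traversal.
#' @param root_scheme `"edge-end"` (default: end of a random giant-component
#'   edge) or `"uniform"` (uniform vertex of the whole graph).
#' @return A `bfs_mapping` object: list with tibbles `tree_points` (x, y,
#'   vertex) and `graph_points` (x, y), the per-vertex vectors `vdeg`
#'   (graph degree) and `vchild` (children on the search tree) in queue
#'   order, `root`, `n`, `n_reached`, `m_reached`, `explored_fraction`.
#' @examples
#' g <- sample_rrg(100, 3, seed = 1)
#' m <- bfs_map(g, seed = 2)
#' nrow(m$graph_points) # 2 * ecount + 1 on a connected graph
#' @export
bfs_map <- function(g, root = NULL, seed = NULL, shuffle = TRUE,
                    root_scheme = c("edge-end", "uniform")) {
  g <- as_multigraph(g)
  root_scheme <- match.arg(root_scheme)
  n <- igraph::vcount(g)
  if (n == 0L) abort("cannot map an empty graph")
  csr <- graph_csr(g)
  with_seed_if(seed, {
    if (is.null(root)) {
      if (csr$m == 0L) {
        inform("graph has no edges; root chosen uniformly among vertices")
        root <- sample.int(n, 1L)
      } else if (root_scheme == "uniform") {
        root <- sample.int(n, 1L)
      } else {
        comp <- igraph::components(g)
        comp_ids <- which(comp$membership == which.max(comp$csize))
        sub <- igraph::induced_subgraph(g, comp_ids)
        el <- igraph::as_edgelist(sub, names = FALSE)
        e <- el[sample.int(nrow(el), 1L), ]
        root <- comp_ids[e[1L + (runif(1) < 0.5)]]
      }
    }
    root <- as.integer(root)
    if (root < 1L || root > n) abort("`root` outside the vertex range")
    res <- cpp_bfs_map(csr$offsets, csr$targets, root - 1L, shuffle)
    n_reached <- length(res$order)
    copies <- length(res$copy_parent_ref)
    tree_points <- tibble(
      x = seq_len(n_reached) / n,
      y = res$tree_parent_pos / n,
      vertex = res$order + 1L
    )
    graph_points <- tibble(
      x = seq_len(copies + 1L) / n,
      y = c(0L, res$copy_parent_ref) / n
    )
    structure(
      list(
        tree_points = tree_points,
        graph_points = graph_points,
        vdeg = res$vdeg, vchild = res$vchild,
        root = root, n = n, n_reached = n_reached,
        m_reached = copies %/% 2L,
        explored_fraction = n_reached / n
      ),
      class = "bfs_mapping"
    )
  })
}

#' @export
print.bfs_mapping <- function(x, ...) {
  cat(sprintf(
    "<bfs_mapping> n = %d, reached %d (S = %.4f), %d graph points, root %d\n",
    x$n, x$n_reached, x$explored_fraction, nrow(x$graph_points), x$root
  ))
  invisible(x)
}

#' Empirical characteristic curve of a BFS mapping
#'
#' Resamples the (nondecreasing) BFS point cloud onto a uniform x grid by
#' last-value interpolation.
#'
#' @param mapping A [bfs_map()] result.
#' @param which `"graph"` (the characteristic curve; default) or `"tree"`.
#' @param grid_size Number of grid samples.
#' @return A [new_bfs_curve()] object in raw queue units.
#' @export
empirical_curve <- function(mapping, which = c("graph", "tree"),
                            grid_size = 1000) {
  stopifnot(inherits(mapping, "bfs_mapping"))
  which <- match.arg(which)
  pts <- if (which == "graph") mapping$graph_points else mapping$tree_points
  s <- mapping$explored_fraction
  z_gc <- if (mapping$n_reached > 0) 2 * mapping$m_reached / mapping$n_reached else 0
  gc <- grid_curve(pts$x, pts$y, max(pts$x), grid_size)
  new_bfs_curve(gc$x, gc$y,
    kind = which, provenance = "empirical-run",
    n = mapping$n, s = s, z_gc = z_gc,
    x_end = max(pts$x), y_end = pts$y[nrow(pts)]
  )
}

#' Map a graph straight to its characteristic curve
#'
#' Convenience wrapper: [bfs_map()] then [empirical_curve()].
#'
#' @inheritParams bfs_map
#' @inheritParams empirical_curve
#' @return A `bfs_curve`.
#' @export
map_curve <- function(g, which = c("graph", "tree"), grid_size = 1000,
                      root = NULL, seed = NULL) {
  empirical_curve(bfs_map(g, root = root, seed = seed),
    which = which, grid_size = grid_size
  )
}

#' Expected degree and search-efficiency profiles along the queue
#'
#' Accumulates per-vertex records (QueueT position x, graph degree, tree
#' degree) over repeated BFS runs and bins them on `[0, 1]`. The search
#' efficiency of a vertex is its count of newly touched children divided by
#' its non-parent edges (`graph degree - 1`), set to 0 for vertices of degree
#' <= 1: the fraction of a vertex's free edges that harvest new vertices.
#' Tree degree is children + 1 (the parent link) for non-root vertices.
#'
#' @param g An igraph graph.
#' @param runs Number of BFS runs to average (>= 1).
#' @param bins Number of position bins on `[0, 1]`.
#' @param seed Optional integer seed.
#' @return An `efficiency_profile` tibble: `x` (bin midpoint), `d_graph`,
#'   `d_tree`, `eta`, `n_obs`.
#' @export
efficiency_profile <- function(g, runs = 10, bins = 100, seed = NULL) {
  stopifnot(runs >= 1)
  g <- as_multigraph(g)
  n <- igraph::vcount(g)
  with_seed_if(seed, {
    acc_dg <- acc_dt <- acc_eta <- acc_n <- numeric(bins)
    for (r in seq_len(runs)) {
      mp <- bfs_map(g)
      pos <- seq_len(mp$n_reached) / n
      dg <- mp$vdeg
      children <- mp$vchild
      dtree <- children + 1
      dtree[1L] <- children[1L] # the root has no parent link
      eta <- ifelse(dg <= 1, 0, children / (dg - 1))
      bin <- pmin(bins, floor(pos * bins) + 1L)
      acc_dg <- acc_dg + as.numeric(tapply(dg, factor(bin, levels = seq_len(bins)), sum, default = 0))
      acc_dt <- acc_dt + as.numeric(tapply(dtree, factor(bin, levels = seq_len(bins)), sum, default = 0))
      acc_eta <- acc_eta + as.numeric(tapply(eta, factor(bin, levels = seq_len(bins)), sum, default = 0))
      acc_n <- acc_n + as.numeric(tapply(rep(1, length(bin)), factor(bin, levels = seq_len(bins)), sum, default = 0))
    }
    out <- tibble(
      x = (seq_len(bins) - 0.5) / bins,
      d_graph = ifelse(acc_n > 0, acc_dg / acc_n, NA_real_),
      d_tree = ifelse(acc_n > 0, acc_dt / acc_n, NA_real_),
      eta = ifelse(acc_n > 0, acc_eta / acc_n, NA_real_),
      n_obs = acc_n
    )
    class(out) <- c("efficiency_profile", class(out))
    attr(out, "runs") <- runs
    attr(out, "n") <- n
    out
  })
}

#' BFS-tree (traceroute) degree distribution
#'
#' Pools the search-tree degrees (children + 1 for non-root vertices) over
#' repeated BFS runs and normalises -- the degree distribution a single-
#' source traceroute-style sampling of the network would observe.
#'
#' @inheritParams efficiency_profile
#' @return A tibble `degree`, `density` (summing to 1).
#' @export
tree_degree_distribution <- function(g, runs = 10, seed = NULL) {
  stopifnot(runs >= 1)
  g <- as_multigraph(g)
  with_seed_if(seed, {
    degs <- integer(0)
    for (r in seq_len(runs)) {
      mp <- bfs_map(g)
      dtree <- mp$vchild + 1L
      dtree[1L] <- mp$vchild[1L]
      degs <- c(degs, dtree)
    }
    tab <- table(degs)
    tibble(
      degree = as.integer(names(tab)),
      density = as.numeric(tab) / length(degs)
    )
  })
}
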