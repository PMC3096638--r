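#' Configuration-model multigraph with a prescribed degree sequence
#'
#' Creates k stubs (edge-endpoint copies) for a vertex of degree k and joins
#' stubs by a uniform random perfect matching, so self-loops and parallel
#' edges can occur. The realised degree sequence (loops counting twice)
#' equals the input exactly.
#'
#' @param degrees Integer vector of degrees; the sum must be even.
#' @param seed Optional integer seed; a fixed seed gives a bit-identical graph.
#' @return An igraph multigraph.
#' @examples
#' g <- configuration_model(rep(3, 6), seed = 1)
#' igraph::ecount(g) # 9
#' @export
configuration_model <- function(degrees, seed = NULL) {
  degrees <- as.integer(degrees)
  if (any(degrees < 0L)) abort("all degrees must be >= 0")
  if (sum(degrees) %% 2L != 0L) {
    abort("the degree sum must be even: stubs cannot be perfectly matched")
  }
  with_seed_if(seed, {
    if (sum(degrees) == 0L) {
      igraph::make_empty_graph(n = length(degrees), directed = FALSE)
    } else {
      igraph::sample_degseq(degrees, method = "configuration")
    }
  })
}

#' Sample a degree sequence from a degree distribution
#'
#' Draws n independent degrees from `dist`. If the sum comes out odd one
#' entry is redrawn until the sum is even; the number of redraws is recorded
#' in the `"resampled"` attribute of the result.
#'
#' @param dist A [degree_dist] object.
#' @param n Number of vertices.
#' @param seed Optional integer seed.
#' @return Integer vector of length n with an even sum.
#' @export
sample_degrees <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "degree_dist"), n >= 1)
  with_seed_if(seed, {
    ks <- seq_along(dist$p) - 1L
    deg <- sample(ks, n, replace = TRUE, prob = dist$p)
    fixes <- 0L
    while (sum(deg) %% 2L != 0L) {
      deg[sample.int(n, 1L)] <- sample(ks, 1L, prob = dist$p)
      fixes <- fixes + 1L
    }
    attr(deg, "resampled") <- fixes
    deg
  })
}

#' Random graph generators for the curve method's reference families
#'
#' * `sample_rrg()`: random k-regular multigraph (configuration model).
#' * `sample_poisson_rg()`: Poisson/Erdos-Renyi random graph with mean degree
#'   z, either as a configuration-model multigraph on Poisson-sampled degrees
#'   (`method = "configuration"`) or as a uniform simple graph with exactly
#'   `round(n z / 2)` edges (`method = "gnm"`).
#' * `sample_plrg()`: power-law distributed random graph with exponent tau on
#'   degrees `[k_min, k_max]` (default cutoff `sqrt(n)`).
#'
#' @param n Number of vertices.
#' @param k,z,tau,k_min,k_max Family parameters.
#' @param method Sampling method for the Poisson graph.
#' @param seed Optional integer seed.
#' @return An igraph graph.
#' @export
sample_rrg <- function(n, k, seed = NULL) {
  configuration_model(rep(k, n), seed = seed)
}

#' @rdname sample_rrg
#' @export
sample_poisson_rg <- function(n, z, method = c("configuration", "gnm"),
                              seed = NULL) {
  method <- match.arg(method)
  with_seed_if(seed, {
    if (method == "gnm") {
      igraph::sample_gnm(n, round(n * z / 2))
    } else {
      deg <- rpois(n, z)
      if (sum(deg) %% 2L != 0L) deg[1L] <- deg[1L] + 1L
      configuration_model(deg)
    }
  })
}

#' @rdname sample_rrg
#' @export
sample_plrg <- function(n, tau, k_min = 2, k_max = floor(sqrt(n)),
                        seed = NULL) {
  dist <- power_law_dist(tau, k_min, k_max)
  with_seed_if(seed, configuration_model(sample_degrees(dist, n)))
}

#' Lattice-embedded random regular graph
#'
#' Superposition of a d-dimensional periodic lattice (side length `side`,
#' torus topology, 2d lattice neighbours per vertex) and an independent
#' r-regular configuration-model graph on the same `side^dim` vertices, so
#' every vertex has constant degree `2 dim + r`. A small-world-like
#' homogeneous network: many local links plus random long-range shortcuts.
#'
#' @param dim Lattice dimension (>= 1).
#' @param side Side length (>= 3); the graph has `side^dim` vertices.
#' @param r Number of long-range links per vertex (>= 0).
#' @param seed Optional integer seed.
#' @return An igraph multigraph.
#' @export
sample_lerrg <- function(dim, side, r, seed = NULL) {
  stopifnot(dim >= 1, side >= 3, r >= 0)
  n <- side^dim
  if ((r * n) %% 2 != 0) {
    abort("r * side^dim must be even so that the r-regular part has a matching")
  }
  lat <- igraph::make_lattice(rep(side, dim), periodic = TRUE)
  el <- igraph::as_edgelist(lat, names = FALSE)
  with_seed_if(seed, {
    if (r > 0) {
      rg <- igraph::sample_degseq(rep(as.integer(r), n), method = "configuration")
      el <- rbind(el, igraph::as_edgelist(rg, names = FALSE))
    }
    as_multigraph(el, n_vertices = n)
  })
}

#' Watts-Strogatz ring with random rewiring
#'
#' Starts from a ring lattice where every vertex is linked to its `k_half`
#' nearest neighbours on each side, then visits each edge once and, with
#' probability `p`, re-attaches its far endpoint to a uniformly chosen vertex,
#' avoiding self-loops and duplicate edges. `p = 0` leaves the ring intact;
#' `p = 1` yields a fully randomised (but still connected-ish) graph.
#'
#' @param n Number of vertices (`n > 2 k_half`).
#' @param k_half Neighbours per side in the starting ring.
#' @param p Rewiring probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return An igraph simple graph.
#' @export
sample_ws_ring <- function(n, k_half, p, seed = NULL) {
  stopifnot(n > 2 * k_half, p >= 0, p <= 1)
  with_seed_if(seed, {
    adj <- vector("list", n)
    for (j in seq_len(k_half)) {
      for (i in seq_len(n)) {
        w <- ((i - 1L + j) %% n) + 1L
        adj[[i]] <- c(adj[[i]], w)
        adj[[w]] <- c(adj[[w]], i)
      }
    }
    for (j in seq_len(k_half)) {
      for (i in seq_len(n)) {
        w <- ((i - 1L + j) %% n) + 1L
        if (w %in% adj[[i]] && runif(1) < p) {
          for (tries in 1:1000) {
            cand <- sample.int(n, 1L)
            if (cand != i && !(cand %in% adj[[i]])) {
              adj[[i]] <- c(adj[[i]][-match(w, adj[[i]])], cand)
              adj[[w]] <- adj[[w]][-match(i, adj[[w]])]
              adj[[cand]] <- c(adj[[cand]], i)
              break
            }
          }
        }
      }
    }
    el <- do.call(rbind, lapply(seq_len(n), function(i) {
      nb <- adj[[i]]
      nb <- nb[nb >= i]
      if (length(nb)) cbind(i, nb) else NULL
    }))
    as_multigraph(el, n_vertices = n)
  })
}

#' Duplication-divergence and preferential-attachment growth models
#'
#' Growth models for protein-interaction-like networks, each starting from a
#' single-edge seed and adding one vertex per step until `n` vertices:
#'
#' * `sample_dmc()` (duplication-mutation-complementation): the new vertex
#'   copies all links of a uniformly chosen anchor; for each neighbour shared
#'   with the anchor, one of the two parallel links (chosen by a fair coin) is
#'   deleted with probability `q_del`; the duplicate-anchor edge is added with
#'   probability `q_con`.
#' * `sample_dmr()` (duplication-mutation-random): the new vertex copies the
#'   anchor's links, deleting each inherited link independently with
#'   probability `q_del`; it then links to every other existing vertex
#'   independently with probability `q_new / n_existing` (about `q_new` new
#'   random links per step regardless of size). No duplicate-anchor mechanism.
#' * `sample_lpa()` (linear preferential attachment): each new vertex attaches
#'   `m` edges to distinct existing vertices chosen proportionally to degree.
#'
#' @param n Target number of vertices (>= 2).
#' @param q_del,q_con,q_new Model probabilities in `[0, 1]`.
#' @param m Links added per step for `sample_lpa()`.
#' @param m_cap Optional edge-count cap; growth is abandoned (returning
#'   `NULL`) as soon as the running edge count exceeds it. Used by the
#'   classifier's size-matched rejection sampling.
#' @param seed Optional integer seed.
#' @return An igraph simple graph, or `NULL` if `m_cap` was exceeded.
#' @export
sample_dmc <- function(n, q_del, q_con, m_cap = Inf, seed = NULL) {
  stopifnot(n >= 2, q_del >= 0, q_del <= 1, q_con >= 0, q_con <= 1)
  with_seed_if(seed, {
    el <- cpp_dmc(as.integer(n), q_del, q_con, m_cap)
    if (is.null(el)) NULL else as_multigraph(el, n_vertices = n)
  })
}

#' @rdname sample_dmc
#' @export
sample_dmr <- function(n, q_del, q_new, m_cap = Inf, seed = NULL) {
  stopifnot(n >= 2, q_del >= 0, q_del <= 1, q_new >= 0, q_new <= 1)
  with_seed_if(seed, {
    el <- cpp_dmr(as.integer(n), q_del, q_new, m_cap)
    if (is.null(el)) NULL else as_multigraph(el, n_vertices = n)
  })
}

#' @rdname sample_dmc
#' @export
sample_lpa <- function(n, m = 1, seed = NULL) {
  stopifnot(n >= 2, m >= 1)
  with_seed_if(seed, as_multigraph(cpp_lpa(as.integer(n), as.integer(m)),
    n_vertices = n
  ))
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

#' Edge-noise perturbations
#'
#' `noise_replace()` (noise 1) deletes `round(fraction * M)` uniformly chosen
#' edges and adds the same number of uniform random vertex pairs (no loops, no
#' duplicates of surviving edges), preserving the edge count but randomising
#' the degree distribution. `noise_rewire()` (noise 2) applies degree-
#' preserving double-edge swaps until `round(fraction * M)` edges have been
#' rewired, so the degree sequence is untouched.
#'
#' @param g An igraph graph.
#' @param fraction Fraction of edges to perturb, in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A perturbed igraph graph.
#' @export
noise_replace <- function(g, fraction, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  g <- as_multigraph(g)
  m <- igraph::ecount(g)
  k <- round(fraction * m)
  if (k == 0L) return(g)
  n <- igraph::vcount(g)
  with_seed_if(seed, {
    el <- igraph::as_edgelist(g, names = FALSE)
    drop <- sample.int(m, k)
    keep <- el[-drop, , drop = FALSE]
    seen <- new.env(hash = TRUE, parent = emptyenv())
    for (key in edge_key(keep[, 1L], keep[, 2L])) assign(key, TRUE, envir = seen)
    added <- matrix(0L, k, 2L)
    for (i in seq_len(k)) {
      ok <- FALSE
      for (tries in 1:1000) {
        ab <- sample.int(n, 2L, replace = TRUE)
        if (ab[1L] == ab[2L]) next
        key <- edge_key(ab[1L], ab[2L])
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          added[i, ] <- ab
          ok <- TRUE
          break
        }
      }
      if (!ok) abort("could not place a replacement edge after 1000 tries")
    }
    as_multigraph(rbind(keep, added), n_vertices = n)
  })
}

#' @rdname noise_replace
#' @export
noise_rewire <- function(g, fraction, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  g <- as_multigraph(g)
  m <- igraph::ecount(g)
  if (m < 2L) {
    warn("graph has fewer than 2 edges; returned unchanged")
    return(g)
  }
  target <- round(fraction * m)
  if (target == 0L) return(g)
  n <- igraph::vcount(g)
  with_seed_if(seed, {
    el <- igraph::as_edgelist(g, names = FALSE)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    for (key in edge_key(el[, 1L], el[, 2L])) assign(key, TRUE, envir = seen)
    rewired <- 0L
    guard <- 0L
    while (rewired < target && guard < 200L * target + 1000L) {
      guard <- guard + 1L
      ij <- sample.int(m, 2L)
      a <- el[ij[1L], ]
      b <- el[ij[2L], ]
      if (runif(1) < 0.5) b <- rev(b)
      # propose (a1, b2) and (b1, a2)
      e1 <- c(a[1L], b[2L])
      e2 <- c(b[1L], a[2L])
      if (e1[1L] == e1[2L] || e2[1L] == e2[2L]) next
      k1 <- edge_key(e1[1L], e1[2L])
      k2 <- edge_key(e2[1L], e2[2L])
      if (k1 == k2 || exists(k1, envir = seen, inherits = FALSE) ||
        exists(k2, envir = seen, inherits = FALSE)) {
        next
      }
      rm(list = c(edge_key(a[1L], a[2L]), edge_key(b[1L], b[2L])), envir = seen)
      assign(k1, TRUE, envir = seen)
      assign(k2, TRUE, envir = seen)
      el[ij[1L], ] <- e1
      el[ij[2L], ] <- e2
      rewired <- rewired + 2L
    }
    as_multigraph(el, n_vertices = n)
  })
}
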