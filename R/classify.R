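#' Size specification for model-generated networks
#'
#' Generated networks are matched to a target scale: every instance has
#' exactly `n_vertices` vertices, and models whose edge count is driven by
#' their own parameters (DMC, DMR) are rejection-sampled until the final
#' edge count falls within `m_tol` of `n_edges` (growth is abandoned early
#' once the running count exceeds the band). The Poisson class gets exactly
#' `n_edges` edges; linear preferential attachment adds `m` links per step.
#'
#' `drosophila_scale()` returns the published sizes of the confidence-
#' filtered *Drosophila melanogaster* protein-interaction network:
#' 3,279 / 4,508 / 6,823 vertices and 2,728 / 4,569 / 19,630 edges at
#' confidence thresholds 0.65 / 0.5 / 0.0.
#'
#' @param n_vertices,n_edges Target vertex and edge counts.
#' @param m_tol Relative half-width of the accepted edge-count band.
#' @param lpa_m Links per step for the LPA model.
#' @return A `scale_spec` list.
#' @export
scale_spec <- function(n_vertices, n_edges, m_tol = 0.1, lpa_m = 1) {
  structure(
    list(
      n_vertices = as.integer(n_vertices), n_edges = as.integer(n_edges),
      m_tol = m_tol, lpa_m = as.integer(lpa_m)
    ),
    class = "scale_spec"
  )
}

#' @rdname scale_spec
#' @param p_cut Confidence threshold: one of 0.65, 0.5, 0.
#' @export
drosophila_scale <- function(p_cut = 0.65) {
  sizes <- list(
    `0.65` = c(3279L, 2728L), `0.5` = c(4508L, 4569L), `0` = c(6823L, 19630L)
  )
  key <- as.character(p_cut)
  if (!key %in% names(sizes)) abort("p_cut must be one of 0.65, 0.5, 0")
  s <- sizes[[key]]
  scale_spec(s[1L], s[2L])
}

#' Generate one size-matched model instance
#'
#' Draws DMC/DMR parameters uniformly in `[0, 1]` per attempt and keeps the
#' first instance whose edge count lands in the scale's accepted band; LPA
#' and PoissonRG instances need no rejection. The accepted parameters and
#' the number of attempts are recorded.
#'
#' @param model One of `"DMC"`, `"DMR"`, `"LPA"`, `"PoissonRG"`.
#' @param scale A [scale_spec()].
#' @param seed Optional integer seed.
#' @param max_tries Attempt cap for the rejection loop.
#' @return A list: `graph`, `model`, `params` (named numeric), `m`, `tries`.
#' @export
generate_instance <- function(model, scale, seed = NULL, max_tries = 10000) {
  model <- match.arg(model, c("DMC", "DMR", "LPA", "PoissonRG"))
  stopifnot(inherits(scale, "scale_spec"))
  n <- scale$n_vertices
  m_target <- scale$n_edges
  lo <- m_target * (1 - scale$m_tol)
  hi <- m_target * (1 + scale$m_tol)
  with_seed_if(seed, {
    if (model == "LPA") {
      g <- sample_lpa(n, m = scale$lpa_m)
      return(list(
        graph = g, model = model, params = c(m = scale$lpa_m),
        m = igraph::ecount(g), tries = 1L
      ))
    }
    if (model == "PoissonRG") {
      g <- igraph::sample_gnm(n, m_target)
      return(list(
        graph = g, model = model, params = c(z = 2 * m_target / n),
        m = m_target, tries = 1L
      ))
    }
    for (try in seq_len(max_tries)) {
      p1 <- runif(1)
      p2 <- runif(1)
      g <- if (model == "DMC") {
        sample_dmc(n, q_del = p1, q_con = p2, m_cap = hi)
      } else {
        sample_dmr(n, q_del = p1, q_new = p2, m_cap = hi)
      }
      if (!is.null(g)) {
        m <- igraph::ecount(g)
        if (m >= lo && m <= hi) {
          params <- if (model == "DMC") {
            c(q_del = p1, q_con = p2)
          } else {
            c(q_del = p1, q_new = p2)
          }
          return(list(graph = g, model = model, params = params, m = m, tries = try))
        }
      }
    }
    abort(paste0("no ", model, " instance matched the size band in ", max_tries, " tries"))
  })
}

# master grid used for batches of classifier curves (rescaled curves end at
# S + O(1/N) <= ~1)
classifier_grid <- function(grid_size) seq(0, 1.02, length.out = grid_size)

# rescale a graph curve by its z_gc and evaluate on the classifier grid
classifier_row <- function(curve, grid) {
  list(
    y = curve_eval(curve, grid),
    end = attr(curve, "x_end") / curve_scale(curve)
  )
}

# distances from one gridded curve to a matrix of gridded curves, integrating
# each pair up to its own max end
batch_distances <- function(y, e, mat, ends, grid) {
  dx <- grid[2L] - grid[1L]
  lim <- pmax(e, ends)
  vapply(seq_len(nrow(mat)), function(j) {
    keep <- grid <= lim[j]
    trapz_uniform(abs(y[keep] - mat[j, keep]), dx)
  }, numeric(1))
}

#' Build a class library of characteristic curves
#'
#' Generates `n_each` size-matched instances per model class and stores one
#' BFS-graph curve per instance (one BFS run each), all on identical grid
#' settings.
#'
#' @param models Character vector of class labels (subset of DMC, DMR, LPA,
#'   PoissonRG).
#' @param n_each Instances per class.
#' @param scale A [scale_spec()]; defaults to [drosophila_scale()].
#' @param seed Optional integer seed for the whole build.
#' @param grid_size Grid resolution shared by every curve.
#' @return A `class_library`: per class a curve matrix with ends, plus the
#'   generation metadata tibble.
#' @export
build_class_library <- function(models = c("DMC", "DMR", "LPA", "PoissonRG"),
                                n_each = 100, scale = drosophila_scale(),
                                seed = NULL, grid_size = 1000) {
  grid <- classifier_grid(grid_size)
  with_seed_if(seed, {
    classes <- list()
    meta <- list()
    for (model in models) {
      ys <- matrix(0, n_each, length(grid))
      ends <- numeric(n_each)
      rows <- vector("list", n_each)
      for (i in seq_len(n_each)) {
        inst <- generate_instance(model, scale)
        cur <- map_curve(inst$graph, grid_size = grid_size)
        cr <- classifier_row(cur, grid)
        ys[i, ] <- cr$y
        ends[i] <- cr$end
        rows[[i]] <- tibble(
          model = model, instance = i, m = inst$m, tries = inst$tries,
          s = attr(cur, "s"), z_gc = attr(cur, "z_gc"),
          params = list(inst$params)
        )
      }
      classes[[model]] <- list(y = ys, end = ends)
      meta[[model]] <- bind_rows(rows)
    }
    structure(
      list(
        classes = classes, labels = models, grid = grid,
        scale = scale, meta = bind_rows(meta)
      ),
      class = "class_library"
    )
  })
}

#' @export
print.class_library <- function(x, ...) {
  sizes <- vapply(x$classes, function(cl) nrow(cl$y), numeric(1))
  cat(
    "<class_library>", paste0(x$labels, " (", sizes, ")", collapse = ", "),
    "\n  scale: n =", x$scale$n_vertices, " m =", x$scale$n_edges, "\n"
  )
  invisible(x)
}

#' Median distance from a curve to a class ensemble
#'
#' The median of the curve-area distances from `curve` to every member of
#' the class (even counts: mean of the central pair) -- the value separating
#' the closer half from the farther half.
#'
#' @param curve A `bfs_curve`.
#' @param library A [build_class_library()] result.
#' @param class A class label present in the library.
#' @return The median distance.
#' @export
median_distance <- function(curve, library, class) {
  stopifnot(inherits(library, "class_library"), class %in% library$labels)
  cr <- classifier_row(curve, library$grid)
  cl <- library$classes[[class]]
  median(batch_distances(cr$y, cr$end, cl$y, cl$end, library$grid))
}

#' Classify a curve or a graph by minimal median distance
#'
#' Computes the median curve distance to every class in the library and
#' returns the label minimising it (deterministic first-label tie-break,
#' with a message when a tie occurs).
#'
#' @param curve A `bfs_curve` (for `classify_curve()`).
#' @param g An igraph graph (for `classify_graph()`; one BFS run maps it).
#' @param library A [build_class_library()] result.
#' @param seed Optional integer seed for the BFS run.
#' @return The winning label, with the named vector of median distances as
#'   attribute `"medians"`.
#' @export
classify_curve <- function(curve, library) {
  stopifnot(inherits(library, "class_library"))
  cr <- classifier_row(curve, library$grid)
  meds <- vapply(library$labels, function(lab) {
    cl <- library$classes[[lab]]
    median(batch_distances(cr$y, cr$end, cl$y, cl$end, library$grid))
  }, numeric(1))
  best <- which(meds == min(meds))
  if (length(best) > 1L) inform("tie in median distances; first label kept")
  label <- library$labels[best[1L]]
  attr(label, "medians") <- meds
  label
}

#' @rdname classify_curve
#' @export
classify_graph <- function(g, library, seed = NULL) {
  classify_curve(map_curve(g, seed = seed), library)
}

#' Classification accuracy matrix over model classes
#'
#' Builds a class library, then generates fresh test instances per class
#' (parameters redrawn uniformly per instance), classifies each by minimal
#' median curve distance, and tabulates row-normalised percentages: entry
#' (i, j) is the percentage of class-i networks classified as class j.
#'
#' @param models Class labels.
#' @param n_library,n_test Library and test instances per class.
#' @param scale A [scale_spec()].
#' @param seed Integer seed; a fixed seed reproduces the matrix exactly.
#' @param grid_size Curve grid resolution.
#' @param library Optionally, a prebuilt [build_class_library()] to reuse.
#' @return An `accuracy_matrix` object: percentage matrix (rows = true
#'   class), instance counts, and the library used.
#' @export
accuracy_matrix <- function(models = c("DMC", "DMR", "LPA", "PoissonRG"),
                            n_library = 100, n_test = 100,
                            scale = drosophila_scale(), seed = NULL,
                            grid_size = 1000, library = NULL) {
  with_seed_if(seed, {
    if (is.null(library)) {
      library <- build_class_library(models,
        n_each = n_library, scale = scale, grid_size = grid_size
      )
    }
    counts <- matrix(0L, length(models), length(models),
      dimnames = list(true = models, predicted = models)
    )
    for (model in models) {
      for (i in seq_len(n_test)) {
        inst <- generate_instance(model, scale)
        lab <- classify_curve(map_curve(inst$graph, grid_size = grid_size), library)
        counts[model, lab] <- counts[model, lab] + 1L
      }
    }
    structure(
      list(
        percent = 100 * counts / n_test, counts = counts,
        n_test = n_test, library = library
      ),
      class = "accuracy_matrix"
    )
  })
}

#' @export
print.accuracy_matrix <- function(x, ...) {
  cat("<accuracy_matrix> (% of row class predicted as column class)\n")
  print(round(x$percent, 1))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.accuracy_matrix <- function(x, ...) {
  df <- as.data.frame.table(x$percent, responseName = "percent")
  as_tibble(df)
}

#' @exportS3Method generics::glance
glance.accuracy_matrix <- function(x, ...) {
  tibble(
    overall_accuracy = mean(diag(x$percent)),
    n_classes = nrow(x$percent),
    n_test_per_class = x$n_test
  )
}

#' Label frequencies of a perturbed network
#'
#' Perturbs `g` with edge noise at each fraction, maps and classifies each
#' perturbed replicate, and returns the label frequency per fraction --
#' the robustness sweep of the classifier under edge replacement (noise 1,
#' which randomises the degree distribution and drives any network towards
#' the Poisson class) or degree-preserving rewiring (noise 2, which is
#' gentler because the degree sequence survives).
#'
#' @param g The network to perturb.
#' @param library A [build_class_library()] result.
#' @param noise `"replace"` or `"rewire"`.
#' @param fractions Noise fractions in `[0, 1]`.
#' @param reps Replicates per fraction.
#' @param seed Optional integer seed.
#' @return A tibble `fraction`, `label`, `freq`.
#' @export
noise_robustness <- function(g, library, noise = c("replace", "rewire"),
                             fractions = seq(0, 1, 0.2), reps = 5,
                             seed = NULL) {
  noise <- match.arg(noise)
  g <- as_multigraph(g)
  fn <- if (noise == "replace") noise_replace else noise_rewire
  with_seed_if(seed, {
    rows <- list()
    for (f in fractions) {
      labs <- character(reps)
      for (r in seq_len(reps)) {
        labs[r] <- classify_graph(fn(g, f), library)
      }
      tab <- table(factor(labs, levels = library$labels))
      rows[[length(rows) + 1L]] <- tibble(
        fraction = f,
        label = names(tab),
        freq = as.numeric(tab) / reps
      )
    }
    bind_rows(rows)
  })
}
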