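#' Analytic characteristic curves for configuration-model random graphs
#'
#' Mean-field theory of the two-queue BFS on a random graph with degree
#' distribution `P(k)`. Exploration is parametrised by the per-stub survival
#' probability: when a fraction x of vertices has been touched the untouched
#' vertices carry degree distribution proportional to `P(k) psi^k` with
#' `g0(psi) = 1 - x`, and the newly touched vertex at queue position x has
#' expected degree `1 + psi g0''(psi) / g0'(psi)`. Working the state
#' evolution through gives closed parametric curves: with `g1 = g0'/z`,
#'
#' * tree curve: `( 1 - g0(g1(psi)), 1 - g0(psi) )`,
#' * graph curve: `( z (1 - psi g1(psi)), z (1 - psi g1inv(psi)) )`,
#'
#' for `psi` running from 1 down to the fixed point [u_star()]. Both curves
#' start at the origin, are nondecreasing, and terminate at the giant-
#' component size S = 1 - g0(u*): the tree curve at (S, S), the graph curve
#' at x_end = z (1 - u*^2) -- the copies generated by the giant component.
#' Curves are evaluated exactly on a uniform x grid by per-point bracketed
#' root finding.
#'
#' @param dist A [degree_dist] with `z > 0` and a giant component.
#' @param grid_size Number of uniform x samples.
#' @return A `bfs_curve` (kind `"tree"` or `"graph"`, provenance
#'   `"analytic-family"`).
#' @examples
#' d <- poisson_dist(4)
#' gc <- graph_curve(d)
#' attr(gc, "s") # about 0.98
#' @export
tree_curve <- function(dist, grid_size = 1000) {
  stopifnot(inherits(dist, "degree_dist"), dist$z > 0)
  us <- u_star(dist)
  s <- 1 - gf_g0(dist, us)
  if (s <= 0) abort("distribution has no giant component; the curve is empty")
  gx <- seq(0, s, length.out = grid_size)
  psi <- vapply(gx, function(x) {
    if (x <= 0) return(1)
    if (x >= s) return(us)
    uniroot(function(u) (1 - gf_g0(dist, gf_g1(dist, u))) - x,
      c(us, 1),
      tol = 1e-12
    )$root
  }, numeric(1))
  gy <- 1 - gf_g0(dist, psi)
  new_bfs_curve(gx, gy,
    kind = "tree", provenance = "analytic-family",
    n = NA_real_, s = s, z_gc = 1, x_end = s, y_end = s
  )
}

#' @rdname tree_curve
#' @export
graph_curve <- function(dist, grid_size = 1000) {
  stopifnot(inherits(dist, "degree_dist"), dist$z > 0)
  us <- u_star(dist)
  s <- 1 - gf_g0(dist, us)
  if (s <= 0) abort("distribution has no giant component; the curve is empty")
  z <- dist$z
  x_end <- z * (1 - us^2)
  gx <- seq(0, x_end, length.out = grid_size)
  psi <- vapply(gx, function(x) {
    if (x <= 0) return(1)
    if (x >= x_end) return(us)
    uniroot(function(u) z * (1 - u * gf_g1(dist, u)) - x,
      c(us, 1),
      tol = 1e-12
    )$root
  }, numeric(1))
  chi <- vapply(psi, function(p) {
    if (p >= 1) return(1)
    if (p <= us) return(us)
    uniroot(function(w) gf_g1(dist, w) - p, c(us, 1), tol = 1e-12)$root
  }, numeric(1))
  gy <- z * (1 - psi * chi)
  new_bfs_curve(gx, gy,
    kind = "graph", provenance = "analytic-family",
    n = NA_real_, s = s, z_gc = x_end / s, x_end = x_end, y_end = x_end
  )
}

#' Closed-form curves for random regular graphs
#'
#' A random k-regular graph (k >= 3, connected with high probability, S = 1)
#' has tree curve `f_T(x) = 1 - (1 - x)^(1/(k-1))` on `[0, 1]` and graph
#' curve `f_G(x) = k (1 - (1 - x/k)^(1/(k-1)))` on `[0, k]`.
#'
#' @param k Fixed degree, `k >= 3`.
#' @param grid_size Number of samples.
#' @return A list with `bfs_curve` elements `tree` and `graph`.
#' @export
rrg_curves <- function(k, grid_size = 1000) {
  if (k < 3) abort("k >= 3 is required for the connected random regular regime")
  list(
    tree = family_curve(k - 1, 1, grid_size = grid_size, kind = "tree"),
    graph = family_curve(k - 1, k, grid_size = grid_size, kind = "graph")
  )
}

#' Principal branch of Lambert's W function
#'
#' Solves `w exp(w) = x` for `x >= -1/e` (the regime the Poisson curves
#' live in: their W arguments are nonnegative, so the principal branch
#' applies throughout). Halley iteration from a piecewise initial guess;
#' vectorised; exact at 0.
#'
#' @param x Numeric vector, each element `>= -1/e`.
#' @return The principal-branch values `W0(x)`.
#' @export
lambert_w0 <- function(x) {
  if (any(x < -exp(-1) - 1e-12)) abort("lambert_w0 requires x >= -1/e")
  x <- pmax(x, -exp(-1))
  # initial guess: series near the branch point, log asymptote for large x
  p <- sqrt(2 * (1 + exp(1) * x))
  w <- ifelse(x < 1, -1 + p - p^2 / 3 + 11 * p^3 / 72,
    log(x) - log(pmax(log(x), 1))
  )
  w[x == 0] <- 0
  for (i in 1:50) {
    ew <- exp(w)
    f <- w * ew - x
    adj <- f / (ew * (w + 1) - (w + 2) * f / (2 * w + 2))
    conv <- abs(f) <= 1e-14 * (1 + abs(x)) | !is.finite(adj)
    w <- ifelse(conv, w, w - adj)
    if (all(conv)) break
  }
  w
}

#' Closed-form curves for Poisson random graphs via Lambert's W
#'
#' For mean degree `z > 1` the giant component has size S solving
#' `1 - S = exp(-z S)`. The tree curve is `f_T(x) = -log(1 - x) / z` on
#' `[0, S]`. The graph curve follows from the stub-survival parametrisation,
#' inverted in closed form with the principal Lambert-W branch:
#' `psi(x) = W0(z exp(z) (1 - x/z)) / z` and
#' `f_G(x) = z (1 - psi) - psi log(psi)`. The W argument is nonnegative on
#' the whole domain, so the principal branch applies throughout.
#'
#' @param z Mean degree, `z > 1` for a giant component.
#' @param grid_size Number of samples.
#' @return A list with `bfs_curve` elements `tree` and `graph`.
#' @export
poisson_curves <- function(z, grid_size = 1000) {
  stopifnot(z > 0)
  if (z <= 1) abort("z <= 1: no giant component, the curves are empty")
  us <- uniroot(function(u) exp(z * (u - 1)) - u, c(0, 1 - 1e-9),
    tol = 1e-12
  )$root
  s <- 1 - us
  tx <- seq(0, s, length.out = grid_size)
  ty <- -log(pmax(1 - tx, 1e-300)) / z
  ty[length(ty)] <- s
  x_end <- z * (1 - us^2)
  gx <- seq(0, x_end, length.out = grid_size)
  w <- lambert_w0(z * exp(z) * (1 - gx / z))
  psi <- pmin(pmax(w / z, us), 1)
  gy <- z * (1 - psi) - psi * log(psi)
  gy[1L] <- 0
  list(
    tree = new_bfs_curve(tx, ty,
      kind = "tree", provenance = "analytic-family",
      n = NA_real_, s = s, z_gc = 1, x_end = s, y_end = s
    ),
    graph = new_bfs_curve(gx, gy,
      kind = "graph", provenance = "analytic-family",
      n = NA_real_, s = s, z_gc = x_end / s, x_end = x_end, y_end = gy[grid_size]
    )
  )
}

#' Slope parameter and closed-form curves for lattice-embedded random
#' regular graphs
#'
#' A LERRG (d-dimensional periodic lattice plus r random links per vertex,
#' constant degree K = 2d + r) explores like a branching flow in which each
#' random-link seed grows a lattice ball whose surface feeds new random
#' links. Summing the ball-surface generating function
#' `((1 + x)/(1 - x))^d` through the renewal equation gives the per-level
#' growth factor lambda as the largest real root of
#'
#' `(lambda - 1)^d = r (lambda + 1)^(d - 1)`.
#'
#' The curves then take the regular-family form with slope `1/lambda`:
#' `f_T(x) = 1 - (1 - x)^(1/lambda)` and
#' `f_G(x) = K (1 - (1 - x/K)^(1/lambda))`, with S = 1. For `d = 1` the root
#' is `lambda = r + 1 = K - 1`, which reproduces the random-regular curves of
#' equal degree exactly.
#'
#' @param d Lattice dimension (>= 1).
#' @param r Random links per vertex (>= 1).
#' @param grid_size Number of samples.
#' @return `lerrg_lambda()`: the slope parameter (a number > 1);
#'   `lerrg_curves()`: a list with `bfs_curve` elements `tree` and `graph`.
#' @export
lerrg_lambda <- function(d, r) {
  stopifnot(d >= 1, r >= 1)
  # ascending coefficients of (x - 1)^d - r (x + 1)^(d - 1)
  a <- choose(d, 0:d) * (-1)^(d - (0:d))
  b <- c(choose(d - 1, 0:(d - 1)), 0)
  roots <- polyroot(a - r * b)
  re <- Re(roots[abs(Im(roots)) < 1e-8 * (1 + abs(roots))])
  if (!length(re)) abort("no real root found for the slope polynomial")
  lambda <- max(re)
  if (lambda <= 1) abort("slope parameter did not exceed 1; invalid (d, r)")
  lambda
}

#' @rdname lerrg_lambda
#' @export
lerrg_curves <- function(d, r, grid_size = 1000) {
  lambda <- lerrg_lambda(d, r)
  k <- 2 * d + r
  list(
    tree = family_curve(lambda, 1, grid_size = grid_size, kind = "tree"),
    graph = family_curve(lambda, k, grid_size = grid_size, kind = "graph")
  )
}

#' The regular curve family
#'
#' The one-parameter family `f(x) = b (1 - (1 - x/b)^(1/lambda))` on
#' `[0, b]` that both random regular graphs (`lambda = k - 1`, `b = k` for
#' the graph curve) and lattice-embedded random regular graphs fall into.
#'
#' @param lambda Slope parameter (> 1 for supercritical exploration).
#' @param b Axis scale (1 for tree curves, the degree K for graph curves).
#' @param grid_size Number of samples.
#' @param kind `"graph"` or `"tree"` label for the resulting curve.
#' @return A `bfs_curve`.
#' @export
family_curve <- function(lambda, b, grid_size = 1000,
                         kind = c("graph", "tree")) {
  stopifnot(lambda >= 1, b > 0)
  kind <- match.arg(kind)
  gx <- seq(0, b, length.out = grid_size)
  gy <- b * (1 - (pmax(1 - gx / b, 0))^(1 / lambda))
  new_bfs_curve(gx, gy,
    kind = kind, provenance = "analytic-family",
    n = NA_real_, s = 1, z_gc = b, x_end = b, y_end = b
  )
}

#' Traceroute (BFS-tree) degree density for the regular curve family
#'
#' Single-source, all-destination traceroute sampling observes the BFS tree.
#' For a network in the regular curve family the expected tree degree of the
#' vertex at queue position x is `t(x) = 1 + lambda (1 - x)^(lambda - 1)`,
#' monotone decreasing, so inverting it maps the uniform position measure
#' into a degree density `p(t)` proportional to `(t - 1)^(-(lambda-2)/(lambda-1))`
#' with a finite cutoff at `1 + lambda` (approached as `1 + lambda (1 -
#' 1/n)^(lambda-1)` at finite n). In the large-lambda limit the exponent
#' tends to 1: homogeneous networks masquerade as power laws under
#' traceroute sampling. Integer-degree masses are obtained exactly by
#' differencing the position function at half-integer degrees.
#'
#' @param n Network size (sets the finite-size cutoff).
#' @param k Degree of a random regular graph (then `lambda = k - 1`), or
#' @param d,r LERRG parameters (then `lambda = lerrg_lambda(d, r)`), or
#' @param lambda The slope parameter directly.
#' @return A tibble `degree`, `density` with attributes `lambda`, `exponent`
#'   and `cutoff`.
#' @export
traceroute_density <- function(n, k = NULL, d = NULL, r = NULL,
                               lambda = NULL) {
  if (is.null(lambda)) {
    if (!is.null(k)) {
      if (k < 3) abort("k >= 3 required")
      lambda <- k - 1
    } else if (!is.null(d) && !is.null(r)) {
      lambda <- lerrg_lambda(d, r)
    } else {
      abort("outside the regular curve family: give k, (d, r), or lambda")
    }
  }
  pos <- function(t) {
    # queue position at which the expected tree degree equals t
    out <- 1 - pmin(pmax((t - 1) / lambda, 0), 1)^(1 / (lambda - 1))
    pmin(out, 1 - 1 / n)
  }
  cutoff <- 1 + lambda * (1 - 1 / n)^(lambda - 1)
  degs <- 1:ceiling(cutoff + 0.5)
  mass <- pos(degs - 0.5) - pos(degs + 0.5)
  keep <- mass > 0
  out <- tibble(degree = degs[keep], density = mass[keep] / sum(mass))
  attr(out, "lambda") <- lambda
  attr(out, "exponent") <- (lambda - 2) / (lambda - 1)
  attr(out, "cutoff") <- cutoff
  out
}

#' Log-log slope of a degree density body
#'
#' Least-squares slope of `log(density)` against `log(degree - x_offset)`
#' over a degree window -- the comparison statistic for power-law bodies of
#' traceroute densities and simulated tree-degree histograms. The analytic
#' density is a power of `degree - 1` (the non-parent tree links), so
#' `x_offset = 1` regresses in the density's natural variable; at degrees
#' well above 1 the two choices coincide.
#'
#' @param density_tbl Tibble with columns `degree` and `density`.
#' @param degrees Degrees to include (the mid-range body).
#' @param x_offset Offset subtracted from the degree before taking logs.
#' @return The fitted slope (typically negative).
#' @export
loglog_slope <- function(density_tbl, degrees, x_offset = 0) {
  d <- density_tbl[density_tbl$degree %in% degrees & density_tbl$density > 0 &
    density_tbl$degree > x_offset, ]
  if (nrow(d) < 2) abort("need at least two positive density points")
  unname(stats::coef(stats::lm(log(d$density) ~ log(d$degree - x_offset)))[2])
}
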