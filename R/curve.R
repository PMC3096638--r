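#' Characteristic curve objects
#'
#' A `bfs_curve` is a tibble of `(x, y)` samples of a nondecreasing curve on a
#' uniform x grid over `[0, x_end]`, in raw queue units: for a tree curve x is
#' QueueT order / N (ending at the explored fraction S), for a graph curve x
#' is QueueG order / N (ending near `(2 M_gc + 1) / N`). Metadata attributes:
#'
#' * `kind`: `"tree"` or `"graph"`,
#' * `provenance`: `"empirical-run"` or `"analytic-family"`,
#' * `n`: vertex count of the mapped graph (`NA` for analytic curves),
#' * `s`: explored / giant-component fraction S,
#' * `z_gc`: average degree of the giant component (the alignment scale),
#' * `x_end`, `y_end`: curve endpoint.
#'
#' @param x,y Numeric vectors (uniform grid, nondecreasing y).
#' @param kind,provenance,n,s,z_gc,x_end,y_end See above.
#' @return A `bfs_curve` tibble.
#' @keywords internal
new_bfs_curve <- function(x, y, kind, provenance, n, s, z_gc,
                          x_end = max(x), y_end = y[length(y)]) {
  out <- tibble(x = as.numeric(x), y = as.numeric(y))
  class(out) <- c("bfs_curve", class(out))
  attr(out, "kind") <- kind
  attr(out, "provenance") <- provenance
  attr(out, "n") <- n
  attr(out, "s") <- s
  attr(out, "z_gc") <- z_gc
  attr(out, "x_end") <- x_end
  attr(out, "y_end") <- y_end
  out
}

curve_meta <- function(curve) {
  tibble(
    kind = attr(curve, "kind"),
    provenance = attr(curve, "provenance"),
    n = attr(curve, "n"),
    s = attr(curve, "s"),
    z_gc = attr(curve, "z_gc"),
    x_end = attr(curve, "x_end"),
    y_end = attr(curve, "y_end")
  )
}

#' @export
print.bfs_curve <- function(x, ...) {
  m <- curve_meta(x)
  cat(sprintf(
    "<bfs_curve: %s, %s>  S = %.4f  z_gc = %.3f  x_end = %.4f  (%d samples)\n",
    m$kind, m$provenance, m$s, m$z_gc, m$x_end, nrow(x)
  ))
  NextMethod()
}

#' @exportS3Method generics::tidy
tidy.bfs_curve <- function(x, ...) {
  xs <- x$x
  ys <- x$y
  tibble(x = xs, y = ys)
}

#' @exportS3Method generics::glance
glance.bfs_curve <- function(x, ...) {
  curve_meta(x)
}

# alignment scale: graph curves are rescaled by the giant component's average
# degree; tree curves are already in vertex-fraction units
curve_scale <- function(curve) {
  if (identical(attr(curve, "kind"), "graph")) attr(curve, "z_gc") else 1
}

# evaluate a (rescaled) curve on an arbitrary grid by last-value (step)
# interpolation, padding beyond the end with the terminal value
curve_eval <- function(curve, grid, scale = curve_scale(curve)) {
  approx(curve$x / scale, curve$y / scale,
    xout = grid, method = "constant",
    f = 0, yleft = 0, yright = attr(curve, "y_end") / scale
  )$y
}

#' Sup-deviation between two curves
#'
#' Evaluates both curves (each rescaled by its own alignment scale) on a
#' common uniform grid and returns the largest absolute vertical difference.
#' The final `trim` fraction of the common span is excluded: the limiting
#' curve of a regular family is vertical at its terminal point, where a
#' finite-N empirical curve necessarily stops short by about `N^(-1/lambda)`
#' -- an extreme-value gap confined to the last handful of vertices that says
#' nothing about agreement of the curve body.
#'
#' @param a,b `bfs_curve` objects.
#' @param grid_size Number of grid points.
#' @param trim Fraction of the span to exclude at the terminal end.
#' @return The sup-deviation (a nonnegative number).
#' @export
curve_deviation <- function(a, b, grid_size = 1000, trim = 0.001) {
  ea <- attr(a, "x_end") / curve_scale(a)
  eb <- attr(b, "x_end") / curve_scale(b)
  hi <- max(ea, eb) * (1 - trim)
  grid <- seq(0, hi, length.out = grid_size)
  max(abs(curve_eval(a, grid) - curve_eval(b, grid)))
}

#' Resample a curve's point cloud onto a uniform grid
#'
#' Internal constructor used by [empirical_curve()] and the analytic
#' families: last-value interpolation of a nondecreasing point sequence.
#' @noRd
grid_curve <- function(px, py, x_end, grid_size) {
  gx <- seq(0, x_end, length.out = grid_size)
  idx <- findInterval(gx, px)
  gy <- c(0, py)[idx + 1L]
  list(x = gx, y = gy)
}
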