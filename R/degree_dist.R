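#' Degree distributions for the analytic curve machinery
#'
#' A `degree_dist` stores probabilities `P(k)` for `k = 0..k_max` together
#' with the mean degree `z`. The analytic characteristic curves are driven by
#' its probability generating function `g0(u) = sum P(k) u^k` and the excess-
#' degree ("edge-following") function `g1(u) = g0'(u) / z`.
#'
#' @param p Numeric vector of probabilities for degrees `0, 1, ..., k_max`;
#'   normalised internally (must be nonnegative and sum to something > 0).
#' @return An object of class `degree_dist`.
#' @examples
#' d <- poisson_dist(2)
#' giant_component_size(d) # about 0.7968
#' @export
degree_dist <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0) || sum(p) <= 0) abort("probabilities must be >= 0 with positive sum")
  p <- p / sum(p)
  ks <- seq_along(p) - 1
  structure(list(p = p, k_max = length(p) - 1L, z = sum(ks * p)),
    class = "degree_dist"
  )
}

#' @rdname degree_dist
#' @param z Mean degree (Poisson); must be > 0.
#' @param k_max Truncation point; defaults to far beyond the 1 - 1e-13
#'   quantile so truncation error is negligible.
#' @export
poisson_dist <- function(z, k_max = NULL) {
  stopifnot(z > 0)
  k_max <- k_max %||% (qpois(1 - 1e-13, z) + 5L)
  degree_dist(dpois(0:k_max, z))
}

#' @rdname degree_dist
#' @param k Fixed degree (regular graph).
#' @export
regular_dist <- function(k) {
  stopifnot(k >= 1)
  degree_dist(c(rep(0, k), 1))
}

#' @rdname degree_dist
#' @param tau Power-law exponent (`tau > 1`); `P(k)` is proportional to
#'   `k^-tau` on `[k_min, k_max]`, with the normalising constant computed
#'   numerically.
#' @param k_min Minimal degree.
#' @export
power_law_dist <- function(tau, k_min, k_max) {
  stopifnot(tau > 1, k_min >= 1, k_max >= k_min)
  p <- numeric(k_max + 1)
  ks <- k_min:k_max
  p[ks + 1] <- ks^(-tau)
  degree_dist(p)
}

#' @export
print.degree_dist <- function(x, ...) {
  cat(
    "<degree_dist> k_max =", x$k_max, " z =", format(x$z, digits = 5),
    " P(0) =", format(x$p[1], digits = 4), "\n"
  )
  invisible(x)
}

# generating function g0, derivatives, and g1 = g0' / z (vectorised in u)
gf_g0 <- function(dist, u) {
  ks <- seq_along(dist$p) - 1
  as.numeric(outer(u, ks, `^`) %*% dist$p)
}

gf_g0p <- function(dist, u) {
  ks <- seq_along(dist$p) - 1
  w <- ks * dist$p
  as.numeric(outer(u, pmax(ks - 1, 0), `^`) %*% w)
}

gf_g0pp <- function(dist, u) {
  ks <- seq_along(dist$p) - 1
  w <- ks * (ks - 1) * dist$p
  as.numeric(outer(u, pmax(ks - 2, 0), `^`) %*% w)
}

gf_g1 <- function(dist, u) gf_g0p(dist, u) / dist$z

#' Fixed point of the edge-following recursion and giant-component size
#'
#' `u_star()` returns the smallest fixed point of `g1` on `[0, 1]` -- the
#' extinction probability of the branching process seen when following a
#' random edge. `giant_component_size()` returns `S = 1 - g0(u_star)`, the
#' vertex fraction of the giant component; it is also the terminal value of
#' the characteristic curves, consistent with the Molloy-Reed / generating-
#' function condition. Subcritical distributions (mean excess degree <= 1)
#' give `u_star = 1` and `S = 0`.
#'
#' @param dist A [degree_dist].
#' @param tol Root-finding tolerance.
#' @return A number in `[0, 1]`.
#' @export
u_star <- function(dist, tol = 1e-10) {
  stopifnot(inherits(dist, "degree_dist"))
  if (dist$z <= 0) return(1)
  mean_excess <- gf_g0pp(dist, 1) / dist$z
  if (mean_excess <= 1 + 1e-12) return(1)
  p1 <- if (length(dist$p) >= 2) dist$p[2] else 0
  if (p1 == 0) return(0) # 0 is a fixed point and the smallest root
  h <- function(u) gf_g1(dist, u) - u
  uniroot(h, c(1e-12, 1 - 1e-9), tol = tol)$root
}

#' @rdname u_star
#' @export
giant_component_size <- function(dist, tol = 1e-10) {
  stopifnot(inherits(dist, "degree_dist"))
  if (dist$z <= 0) return(0)
  us <- u_star(dist, tol = tol)
  max(0, 1 - gf_g0(dist, us))
}
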