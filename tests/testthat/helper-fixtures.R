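# A 3-regular 6-vertex multigraph whose ordered adjacency reproduces the
# worked BFS example: root 3 explores neighbours (2, 4, 5); vertex 2 explores
# (3, 5, 6); vertex 4 explores (3, 1, 1) -- the parallel pair 4-1 closes the
# degree sequence. Edge insertion order fixes the neighbour order used when
# bfs_map() runs with shuffle = FALSE.
fig_example_graph <- function() {
  as_multigraph(rbind(
    c(3, 2), c(3, 4), c(3, 5),
    c(2, 5), c(2, 6), c(5, 6),
    c(4, 1), c(4, 1), c(1, 6)
  ))
}

# independent giant-component oracle: fixed-point iteration of the
# edge-following recursion u <- g1(u) from u = 0 (monotone convergence to the
# smallest fixed point), then S = 1 - g0(u)
gc_size_oracle <- function(p) {
  p <- p / sum(p)
  ks <- seq_along(p) - 1
  z <- sum(ks * p)
  if (z == 0) return(0)
  g0 <- function(u) sum(p * u^ks)
  g1 <- function(u) sum(ks * p * u^pmax(ks - 1, 0) * (ks >= 1)) / z
  u <- 0
  for (i in 1:10000) {
    u_new <- g1(u)
    if (abs(u_new - u) < 1e-15) break
    u <- u_new
  }
  max(0, 1 - g0(u))
}

# build a minimal class_library whose members are flat curves at given
# heights, for exercising the median-distance conventions in isolation
flat_library <- function(heights_by_class, grid_size = 500) {
  grid <- seq(0, 1.02, length.out = grid_size)
  classes <- lapply(heights_by_class, function(hs) {
    list(
      y = do.call(rbind, lapply(hs, function(h) rep(h, grid_size))),
      end = rep(1.02, length(hs))
    )
  })
  structure(
    list(
      classes = classes, labels = names(heights_by_class), grid = grid,
      scale = scale_spec(10, 10), meta = tibble::tibble()
    ),
    class = "class_library"
  )
}

flat_curve <- function(h, grid_size = 500) {
  netcurve:::new_bfs_curve(
    x = seq(0, 1.02, length.out = grid_size),
    y = rep(h, grid_size),
    kind = "graph", provenance = "empirical-run",
    n = 10, s = 1, z_gc = 1, x_end = 1.02, y_end = h
  )
}
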