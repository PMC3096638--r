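test_that("the worked traversal reproduces every published coordinate", {
  g <- fig_example_graph()
  m <- bfs_map(g, root = 3, shuffle = FALSE)

  # QueueT order 3, 2, 4, 5, 6, 1
  expect_equal(m$tree_points$vertex, c(3, 2, 4, 5, 6, 1))
  # vertex 2 at (2/6, 1/6), vertex 5 at (4/6, 1/6)
  expect_equal(m$tree_points$x[2], 2 / 6)
  expect_equal(m$tree_points$y[2], 1 / 6)
  expect_equal(m$tree_points$x[4], 4 / 6)
  expect_equal(m$tree_points$y[4], 1 / 6)
  # vertex 6 pushed fifth with parent 2: (5/6, 2/6)
  expect_equal(m$tree_points$x[5], 5 / 6)
  expect_equal(m$tree_points$y[5], 2 / 6)

  # copies of 3, 5, 6 pushed while exploring vertex 2: QueueG positions
  # 5, 6, 7 with the reference copy of 2 at position 2
  expect_equal(m$graph_points$x[5:7], c(5, 6, 7) / 6)
  expect_equal(m$graph_points$y[5:7], rep(2 / 6, 3))
  # copy of 2 pushed while exploring vertex 5 (reference copy at 4): (12/6, 4/6)
  expect_equal(m$graph_points$x[12], 12 / 6)
  expect_equal(m$graph_points$y[12], 4 / 6)
  # 2M + 1 copies in total on a connected multigraph
  expect_equal(nrow(m$graph_points), 2 * 9 + 1)
})

test_that("conservation, diagonal bound and monotonicity hold on random maps", {
  for (seed in 1:3) {
    g <- sample_plrg(300, 2.5, 2, 17, seed = seed)
    m <- bfs_map(g, seed = seed + 10)
    gc <- giant_component(g)
    n_gc <- igraph::vcount(gc$graph)
    m_gc <- igraph::ecount(gc$graph)
    expect_equal(m$n_reached, n_gc)
    expect_equal(nrow(m$graph_points), 2 * m_gc + 1)
    expect_equal(m$explored_fraction, n_gc / igraph::vcount(g))
    # parents strictly precede children in both queues
    expect_true(all(m$tree_points$y < m$tree_points$x))
    expect_true(all(m$graph_points$y < m$graph_points$x))
    expect_true(all(diff(m$tree_points$y) >= 0))
    expect_true(all(diff(m$graph_points$y) >= 0))
  }
})

test_that("the same seed replays the identical mapping and curve", {
  g <- sample_poisson_rg(500, 2, seed = 4)
  m1 <- bfs_map(g, seed = 7)
  m2 <- bfs_map(g, seed = 7)
  expect_identical(m1$tree_points, m2$tree_points)
  expect_identical(m1$graph_points, m2$graph_points)
  c1 <- empirical_curve(m1)
  c2 <- empirical_curve(m2)
  expect_identical(c1$y, c2$y)
})

test_that("a single run on a large regular graph lies on the analytic curve", {
  g <- sample_rrg(10000, 3, seed = 1)
  m <- bfs_map(g, seed = 2)
  th <- rrg_curves(3)
  expect_lt(curve_deviation(empirical_curve(m, "tree"), th$tree), 0.02)
  expect_lt(curve_deviation(empirical_curve(m, "graph"), th$graph), 0.02)
  # graph curve of a connected graph ends at x about k with terminal y near x
  cg <- empirical_curve(m, "graph")
  expect_equal(attr(cg, "x_end"), 3 + 1 / 10000)
  expect_equal(attr(cg, "s"), 1)
})

test_that("giant-component fraction of a sparse Poisson graph matches the
           fixed-point prediction", {
  g <- sample_poisson_rg(100000, 2, seed = 3)
  s_oracle <- gc_size_oracle(dpois(0:30, 2))
  expect_lt(abs(giant_component(g)$fraction - s_oracle), 0.01)
  expect_equal(round(s_oracle, 4), 0.7968)
})

test_that("two cliques split into the right giant fraction", {
  g <- as_multigraph(rbind(
    t(utils::combn(1:5, 2)), t(utils::combn(6:8, 2))
  ))
  gc <- giant_component(g)
  expect_equal(gc$fraction, 5 / 8)
  expect_equal(igraph::vcount(gc$graph), 5)
})

test_that("efficiency profiles are bounded and ordered", {
  g <- sample_rrg(2000, 4, seed = 1)
  ep <- efficiency_profile(g, runs = 5, bins = 50, seed = 2)
  ok <- !is.na(ep$eta)
  expect_true(all(ep$eta[ok] >= 0 & ep$eta[ok] <= 1))
  expect_true(all(ep$d_tree[ok] <= ep$d_graph[ok] + 1e-12))
  # on a regular random graph the efficiency declines along the queue
  expect_lt(cor(ep$x[ok], ep$eta[ok]), -0.9)
})

test_that("a lattice explores less efficiently early, more efficiently late,
           than its random counterpart", {
  lat <- igraph::make_lattice(c(40, 40), periodic = TRUE)
  rc <- random_counterpart(lat, seed = 1)
  pl <- efficiency_profile(lat, runs = 5, bins = 20, seed = 2)
  pr <- efficiency_profile(rc, runs = 5, bins = 20, seed = 3)
  early <- 1:4
  late <- 13:18
  expect_lt(mean(pl$eta[early]), mean(pr$eta[early]))
  expect_gt(mean(pl$eta[late], na.rm = TRUE), mean(pr$eta[late], na.rm = TRUE))
})

test_that("tree-degree histograms are normalised and catch the star centre", {
  star <- igraph::make_star(10, mode = "undirected", center = 1)
  h <- tree_degree_distribution(star, runs = 1, seed = 1)
  expect_equal(sum(h$density), 1)
  expect_true(9 %in% h$degree) # the centre touches everyone
  expect_equal(h$density[h$degree == 1], 9 / 10)

  g <- sample_rrg(1000, 5, seed = 2)
  h2 <- tree_degree_distribution(g, runs = 3, seed = 3)
  expect_equal(sum(h2$density), 1)
  expect_true(max(h2$degree) <= 5)
})

test_that("degenerate inputs are handled as contracted", {
  expect_error(bfs_map(sample_rrg(10, 3, seed = 1), root = 11), "range")
  edgeless <- igraph::make_empty_graph(5, directed = FALSE)
  expect_message(m <- bfs_map(edgeless, seed = 1), "no edges")
  expect_equal(m$n_reached, 1L)
})
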