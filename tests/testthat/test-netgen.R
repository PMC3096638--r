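test_that("configuration model realises the degree sequence exactly", {
  g <- configuration_model(rep(3, 6), seed = 1)
  expect_equal(igraph::ecount(g), 9)
  expect_equal(unname(igraph::degree(g, loops = TRUE)), rep(3, 6))

  g0 <- configuration_model(c(0, 0, 0))
  expect_equal(igraph::ecount(g0), 0)
  expect_equal(igraph::vcount(g0), 3)

  gl <- configuration_model(2) # only possible matching: a single self-loop
  expect_equal(igraph::ecount(gl), 1)
  expect_true(igraph::which_loop(gl))

  expect_error(configuration_model(c(3, 2)), "even")

  degs <- sample_degrees(power_law_dist(2.5, 2, 20), 500, seed = 2)
  g2 <- configuration_model(degs, seed = 3)
  expect_equal(sort(unname(igraph::degree(g2, loops = TRUE))), sort(as.integer(degs)))
})

test_that("sampled degree sequences respect the distribution", {
  d <- sample_degrees(regular_dist(4), 50, seed = 1)
  expect_true(all(d == 4))

  d2 <- sample_degrees(power_law_dist(2.5, 2, 31), 2000, seed = 2)
  expect_true(all(d2 >= 2 & d2 <= 31))
  expect_equal(sum(d2) %% 2, 0)

  z <- 3
  d3 <- sample_degrees(poisson_dist(z), 5000, seed = 3)
  se <- sqrt(z / 5000)
  expect_lt(abs(mean(d3) - z), 3 * se)
})

test_that("random 3-regular graphs are almost surely one giant component", {
  g <- sample_rrg(10000, 3, seed = 5)
  expect_gt(giant_component(g)$fraction, 0.99)
})

test_that("LERRG vertices all carry degree 2 dim + r", {
  ring <- sample_lerrg(1, 10, 0)
  expect_true(all(igraph::degree(ring) == 2))

  g <- sample_lerrg(2, 10, 2, seed = 1)
  expect_equal(igraph::vcount(g), 100)
  expect_true(all(igraph::degree(g, loops = TRUE) == 6))

  expect_error(sample_lerrg(1, 9, 3), "even")
})

test_that("Watts-Strogatz rewiring behaves at its extremes", {
  ring <- sample_ws_ring(50, 2, 0, seed = 1)
  expect_true(all(igraph::degree(ring) == 4))
  expect_equal(igraph::ecount(ring), 100)

  full <- sample_ws_ring(200, 3, 1, seed = 2)
  expect_gt(stats::var(igraph::degree(full)), 0) # no longer constant
  expect_equal(igraph::ecount(full), 600) # edge count preserved

  c0 <- igraph::transitivity(sample_ws_ring(300, 3, 0, seed = 3))
  c1 <- igraph::transitivity(sample_ws_ring(300, 3, 1, seed = 4))
  expect_gt(c0, c1)
})

test_that("DMC parameter extremes give the hand-derived graphs", {
  # never delete, always connect the duplicate pair: completeness is inherited
  g <- sample_dmc(40, q_del = 0, q_con = 1, seed = 1)
  expect_equal(igraph::ecount(g), 40 * 39 / 2)
  expect_true(all(igraph::degree(g) == 39))

  # every shared pair loses one side and no duplicate-anchor edge appears:
  # duplication is edge-neutral, so the seed edge is all that ever exists
  g2 <- sample_dmc(100, q_del = 1, q_con = 0, seed = 2)
  expect_equal(igraph::ecount(g2), 1)

  g3 <- sample_dmc(200, q_del = 0.4, q_con = 0.3, seed = 3)
  expect_equal(igraph::vcount(g3), 200)
  expect_false(any(igraph::which_multiple(g3)))
  expect_false(any(igraph::which_loop(g3)))
})

test_that("DMR parameter extremes and the new-link rate check out", {
  # delete everything, create nothing: every added vertex stays isolated
  g <- sample_dmr(150, q_del = 1, q_new = 0, seed = 1)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(max(igraph::components(g)$csize), 2)

  # pure duplication: no isolated vertices can appear
  g2 <- sample_dmr(100, q_del = 0, q_new = 0, seed = 2)
  expect_true(all(igraph::degree(g2) >= 1))

  # with total deletion, edges added are exactly the Binomial random links:
  # about q_new per step independent of size
  q_new <- 0.5
  n <- 2000
  g3 <- sample_dmr(n, q_del = 1, q_new = q_new, seed = 3)
  extra <- igraph::ecount(g3) - 1
  expect_lt(abs(extra - q_new * (n - 2)), 4 * sqrt(q_new * (n - 2)))
  expect_false(any(igraph::which_multiple(g3)))
})

test_that("linear preferential attachment grows the expected structure", {
  g <- sample_lpa(500, m = 1, seed = 1)
  expect_equal(igraph::ecount(g), 499) # a tree
  expect_equal(igraph::count_components(g), 1)

  g2 <- sample_lpa(400, m = 3, seed = 2)
  expect_true(all(igraph::degree(g2)[3:400] >= 3))

  g3 <- sample_lpa(3000, m = 1, seed = 3)
  expect_gt(max(igraph::degree(g3)), 5 * mean(igraph::degree(g3)))
})

test_that("edge replacement noise preserves edge counts only", {
  g <- igraph::simplify(sample_poisson_rg(400, 3, seed = 1))
  expect_identical(noise_replace(g, 0), g)
  for (f in c(0.2, 0.7, 1)) {
    gn <- noise_replace(g, f, seed = round(10 * f))
    expect_equal(igraph::ecount(gn), igraph::ecount(g))
    expect_false(any(igraph::which_loop(gn)))
    expect_false(any(igraph::which_multiple(gn)))
  }
})

test_that("degree-preserving rewiring keeps the degree histogram exact", {
  g <- sample_plrg(400, 2.5, 2, 20, seed = 1)
  g <- igraph::simplify(g)
  expect_identical(noise_rewire(g, 0), g)
  for (f in c(0.3, 1)) {
    gn <- noise_rewire(g, f, seed = round(10 * f))
    expect_identical(
      sort(unname(igraph::degree(g))),
      sort(unname(igraph::degree(gn)))
    )
  }
  tiny <- as_multigraph(rbind(c(1, 2)))
  expect_warning(noise_rewire(tiny, 0.5), "fewer than 2")
})

test_that("a fixed seed reproduces a generator bit for bit", {
  for (gen in list(
    function(s) sample_dmc(100, 0.3, 0.7, seed = s),
    function(s) sample_dmr(100, 0.3, 0.7, seed = s),
    function(s) sample_lpa(100, 2, seed = s),
    function(s) sample_lerrg(2, 8, 2, seed = s),
    function(s) sample_ws_ring(60, 2, 0.3, seed = s)
  )) {
    e1 <- igraph::as_edgelist(gen(99))
    e2 <- igraph::as_edgelist(gen(99))
    expect_identical(e1, e2)
  }
})
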