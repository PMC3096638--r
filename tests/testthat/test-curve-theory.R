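test_that("giant-component sizes match the generating-function oracle", {
  expect_equal(giant_component_size(poisson_dist(2)),
    gc_size_oracle(dpois(0:40, 2)),
    tolerance = 1e-6
  )
  expect_equal(round(giant_component_size(poisson_dist(2)), 4), 0.7968)
  expect_equal(giant_component_size(poisson_dist(0.5)), 0)
  expect_equal(giant_component_size(regular_dist(3)), 1)

  withr::with_seed(42, {
    for (i in 1:20) {
      kmax <- sample(3:9, 1)
      p <- runif(kmax + 1)^2
      s_pkg <- giant_component_size(degree_dist(p))
      s_orc <- gc_size_oracle(p)
      expect_lt(abs(s_pkg - s_orc), 1e-6)
    }
  })
})

test_that("the general solution collapses onto the regular closed form", {
  for (k in c(4, 6)) {
    d <- regular_dist(k)
    closed <- rrg_curves(k)
    expect_lt(max(abs(tree_curve(d)$y - closed$tree$y)), 1e-8)
    expect_lt(max(abs(graph_curve(d)$y - closed$graph$y)), 1e-8)
  }
})

test_that("the general solution collapses onto the Lambert-W closed form", {
  z <- 4
  closed <- poisson_curves(z)
  general_t <- tree_curve(poisson_dist(z))
  general_g <- graph_curve(poisson_dist(z))
  # grids differ slightly through S truncation; compare via interpolation
  expect_lt(
    max(abs(approx(general_t$x, general_t$y, xout = closed$tree$x, rule = 2)$y
    - closed$tree$y)), 1e-6
  )
  expect_lt(
    max(abs(approx(general_g$x, general_g$y, xout = closed$graph$x, rule = 2)$y
    - closed$graph$y)), 1e-6
  )
  expect_equal(attr(closed$graph, "s"), giant_component_size(poisson_dist(z)),
    tolerance = 1e-8
  )
})

test_that("regular curves obey their boundary contract", {
  cs <- rrg_curves(3)
  expect_equal(cs$tree$y[1], 0)
  expect_equal(cs$tree$y[1000], 1)
  expect_equal(attr(cs$graph, "x_end"), 3) # copies exhausted at x = k
  expect_equal(cs$graph$y[1000], 3)
  expect_error(rrg_curves(2), "k >= 3")

  # faster exploration at higher degree: vertices are touched by earlier
  # parents, so the k = 10 tree curve lies below the k = 3 curve throughout
  # the interior (equivalently, the touched fraction grows faster)
  t3 <- rrg_curves(3)$tree
  t10 <- rrg_curves(10)$tree
  inner <- 2:999
  expect_true(all(t10$y[inner] < t3$y[inner]))
})

test_that("Poisson curves behave across the density range", {
  expect_equal(attr(poisson_curves(2)$graph, "s"), 0.7968, tolerance = 1e-4)
  expect_gt(attr(poisson_curves(30)$graph, "s"), 1 - 1e-9)
  expect_error(poisson_curves(0.8), "giant")
})

test_that("every analytic curve is nondecreasing from zero to S", {
  dists <- list(
    poisson_dist(3), regular_dist(5), power_law_dist(2.5, 2, 50),
    degree_dist(c(0, 0.1, 0.5, 0.2, 0.2))
  )
  for (d in dists) {
    tc <- tree_curve(d)
    gc <- graph_curve(d)
    s <- giant_component_size(d)
    expect_equal(tc$y[1], 0)
    expect_equal(gc$y[1], 0)
    expect_true(all(diff(tc$y) >= -1e-12))
    expect_true(all(diff(gc$y) >= -1e-12))
    expect_equal(tc$y[nrow(tc)], s, tolerance = 1e-8)
    expect_equal(attr(tc, "x_end"), s, tolerance = 1e-8)
    us <- u_star(d)
    expect_equal(attr(gc, "x_end"), d$z * (1 - us^2), tolerance = 1e-8)
  }
})

test_that("the lattice-embedded slope parameter solves its polynomial", {
  expect_equal(lerrg_lambda(1, 6), 7) # d = 1: lambda = r + 1 = K - 1
  expect_equal(lerrg_lambda(2, 2), 2 + sqrt(5), tolerance = 1e-10)
  lam <- lerrg_lambda(3, 2)
  expect_lt(abs((lam - 1)^3 - 2 * (lam + 1)^2), 1e-8)

  # d = 1 reproduces the random-regular closed form exactly
  lc <- lerrg_curves(1, 6)
  rc <- rrg_curves(8)
  expect_equal(lc$tree$y, rc$tree$y)
  expect_equal(lc$graph$y, rc$graph$y)

  # terminal value S = 1 for valid (d, r)
  for (dr in list(c(1, 2), c(2, 2), c(2, 4), c(3, 2))) {
    cs <- lerrg_curves(dr[1], dr[2])
    expect_equal(cs$tree$y[1000], 1)
    expect_equal(attr(cs$graph, "s"), 1)
  }
})

test_that("traceroute densities normalise and expose the large-degree law", {
  td <- traceroute_density(1e5, k = 6)
  expect_equal(sum(td$density), 1)
  expect_lt(attr(td, "cutoff"), 6 + 1e-6) # cutoff at 1 + lambda = k
  td2 <- traceroute_density(1e6, lambda = 1e6)
  expect_equal(attr(td2, "exponent"), 1, tolerance = 1e-5)
  expect_error(traceroute_density(1e4), "family")
})
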