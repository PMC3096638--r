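write_records <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

test_that("weighted edge lists parse with line-aware errors", {
  p <- write_records(c("# comment", "a\tb\t0.2", "b\tc\t0.6", "c\td\t0.9"))
  el <- read_weighted_edgelist(p)
  expect_equal(nrow(el), 3)
  expect_equal(el$confidence, c(0.2, 0.6, 0.9))

  p2 <- write_records(c("a b", "b c"))
  el2 <- read_weighted_edgelist(p2, col_conf = NA)
  expect_true(all(el2$confidence == 1))

  p3 <- write_records(c("a\tb\t0.5", "b\tc\t1.5"))
  expect_error(read_weighted_edgelist(p3), "outside \\[0, 1\\].*2")

  p4 <- write_records(c("a\tb\t0.5", "lonely"))
  expect_error(read_weighted_edgelist(p4), "malformed.*2")
})

test_that("filtering matches the hand-worked oracle", {
  el <- tibble::tibble(
    a = c("a", "a", "a", "c", "e"),
    b = c("b", "b", "a", "d", "f"),
    confidence = c(0.7, 0.8, 0.9, 0.3, 0.65)
  )
  g <- filter_network(el, 0.65)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::V(g)$name, c("a", "b", "e", "f"))

  clean <- tibble::tibble(
    a = c("x", "y"), b = c("y", "z"), confidence = c(0.1, 0.9)
  )
  g0 <- filter_network(clean, 0)
  expect_equal(igraph::ecount(g0), 2)
})

test_that("filtering is idempotent and monotone in the threshold", {
  p <- make_fixture("ppi-like", n = 300, seed = 2)
  el <- read_weighted_edgelist(p)
  g1 <- filter_network(el, 0.65)
  back <- tibble::tibble(
    a = igraph::as_edgelist(g1)[, 1], b = igraph::as_edgelist(g1)[, 2],
    confidence = 1
  )
  g2 <- filter_network(back, 0.65)
  expect_equal(igraph::vcount(g2), igraph::vcount(g1))
  expect_equal(igraph::ecount(g2), igraph::ecount(g1))

  cuts <- c(0, 0.3, 0.65, 0.9)
  sizes <- t(vapply(cuts, function(pc) {
    g <- filter_network(el, pc)
    c(igraph::vcount(g), igraph::ecount(g))
  }, numeric(2)))
  expect_true(all(diff(sizes[, 1]) <= 0))
  expect_true(all(diff(sizes[, 2]) <= 0))
})

test_that("the interaction-style fixture exercises every cleaning rule", {
  p <- make_fixture("ppi-like", n = 300, seed = 5)
  lines <- readLines(p)
  recs <- do.call(rbind, strsplit(grep("^#", lines, value = TRUE, invert = TRUE), "\t"))
  expect_gte(sum(recs[, 1] == recs[, 2]), 1) # self-loop present
  keys <- paste(pmin(recs[, 1], recs[, 2]), pmax(recs[, 1], recs[, 2]))
  expect_gte(sum(duplicated(keys)), 1) # duplicate record present
  p2 <- make_fixture("ppi-like", n = 300, seed = 5, dir = tempfile("fx2"))
  expect_identical(lines, readLines(p2)) # same seed, byte-identical
})

test_that("the quartet fixture matches average degrees within 5%", {
  paths <- make_fixture("quartet", n = 900, seed = 3)
  zs <- vapply(paths, function(p) graph_info(read_edgelist(p))$avg_degree,
    numeric(1)
  )
  ns <- vapply(paths, function(p) igraph::vcount(read_edgelist(p)), numeric(1))
  expect_equal(length(unique(ns)), 1)
  expect_lt(max(zs) / min(zs), 1.05)
})

test_that("model evaluation recovers the generating model of a target", {
  target <- sample_lpa(800, m = 1, seed = 7)
  rep <- evaluate_models(target,
    models = c("LPA", "PoissonRG"),
    n_instances = 9, seed = 8
  )
  expect_equal(rep$table$model[1], "LPA")
  expect_true(all(rep$table$rank == 1:2))

  one <- evaluate_models(target,
    models = "PoissonRG", n_instances = 1, seed = 9
  )
  expect_equal(one$table$median_distance, one$distances$distance)

  g <- glance(rep)
  expect_equal(g$best_model, "LPA")
})
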