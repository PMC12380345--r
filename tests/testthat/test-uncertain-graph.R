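test_that("probabilistic edge lists parse, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "a b 0.5", "b c 1.0"), f)
  g <- read_probabilistic_edgelist(f)
  expect_s3_class(g, "uncertain_graph")
  expect_length(g$nodes, 3)
  expect_equal(nrow(g$edges), 2)
  ab <- which(g$nodes[g$edges[, 1]] == "a")
  expect_equal(g$prob[ab], 0.5)

  writeLines("a a 0.5", f)
  expect_error(read_probabilistic_edgelist(f), "self-loop")
  writeLines("a b 1.3", f)
  expect_error(read_probabilistic_edgelist(f), "probability")
  writeLines("a b 0", f)
  expect_error(read_probabilistic_edgelist(f), "probability")
  writeLines(c("a b 0.5", "b a 0.7"), f)
  expect_error(read_probabilistic_edgelist(f), "duplicate")
  writeLines("a b", f)
  expect_error(read_probabilistic_edgelist(f), "expected 3")
  writeLines("a b zero.five", f)
  expect_error(read_probabilistic_edgelist(f), "malformed")

  # write then read is the identity on the (named) edge set
  g2 <- make_uncertain_er(50, 4, rng_seed = 3)
  write_probabilistic_edgelist(g2, f)
  g3 <- read_probabilistic_edgelist(f)
  keyed <- function(g) {
    k <- paste(g$nodes[g$edges[, 1]], g$nodes[g$edges[, 2]])
    setNames(g$prob, k)[order(k)]
  }
  expect_identical(keyed(g3), keyed(g2))
})

test_that("deterministic edge lists round-trip, including the empty graph", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tri <- igraph::make_graph(~ a - b, b - c, c - a)
  write_edgelist(tri, f)
  expect_length(readLines(f), 3)
  back <- read_edgelist(f)
  expect_true(igraph::isomorphic(back, tri))

  write_edgelist(igraph::make_empty_graph(0, directed = FALSE), f)
  expect_length(readLines(f), 0)
  expect_equal(igraph::vcount(read_edgelist(f)), 0)

  g <- igraph::sample_gnm(50, 80)
  igraph::V(g)$name <- sprintf("x%02d", 1:50)
  write_edgelist(g, f)
  g2 <- read_edgelist(f)
  key <- function(gr) {
    el <- igraph::as_edgelist(gr)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(key(g2), key(g))
})

test_that("ER fixture has the exact requested edge count and uniform probabilities", {
  g <- make_uncertain_er(200, 5, rng_seed = 1)
  expect_equal(nrow(g$edges), 500)  # G(n, m): average degree exactly five
  expect_length(g$nodes, 200)

  g0 <- make_uncertain_er(2, 0)
  expect_length(g0$nodes, 2)
  expect_equal(nrow(g0$edges), 0)

  # probabilities are uniform on (0, 1]: mean 0.5 within 3 standard errors
  set.seed(2)
  big <- make_uncertain_er(200, 100)  # 10^4 edges
  expect_equal(nrow(big$edges), 10000)
  se <- sqrt(1 / 12 / 10000)
  expect_lt(abs(mean(big$prob) - 0.5), 3 * se)
  expect_true(all(big$prob > 0 & big$prob <= 1))
})

test_that("BA fixture is heavy-tailed relative to a matched ER fixture", {
  g <- make_uncertain_ba(1000, 5, rng_seed = 1)
  expect_equal(nrow(g$edges), 2500)
  expect_length(g$nodes, 1000)

  small <- make_uncertain_ba(3, 2, rng_seed = 1)
  expect_length(small$nodes, 3)

  set.seed(4)
  wins <- vapply(1:40, function(i) {
    ba <- make_uncertain_ba(500, 5)
    er <- make_uncertain_er(500, 5)
    maxdeg <- function(x) max(tabulate(c(x$edges)))
    maxdeg(ba) > maxdeg(er)
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})

test_that("star fixture has one hub and uniform probability", {
  g <- make_uncertain_star(31, 0.7)
  deg <- tabulate(c(g$edges), nbins = 31)
  expect_equal(max(deg), 30)
  expect_equal(sum(deg == 1), 30)
  expect_true(all(g$prob == 0.7))

  g2 <- make_uncertain_star(2, 1.0)
  expect_equal(nrow(g2$edges), 1)
  g5 <- make_uncertain_star(5, 0.5)
  expect_equal(nrow(g5$edges), 4)
  expect_true(all(g5$prob == 0.5))
})

test_that("fixture generators are seed-reproducible", {
  expect_identical(make_uncertain_er(60, 4, rng_seed = 9),
                   make_uncertain_er(60, 4, rng_seed = 9))
  expect_identical(make_uncertain_ba(60, 4, rng_seed = 9),
                   make_uncertain_ba(60, 4, rng_seed = 9))
})
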