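test_that("certain targets have zero spread and exact counts", {
  g <- igraph::make_graph(~ a - b, b - c, c - a, c - d)
  st <- certain_target(g, S = 10, n_g = 4)
  expect_equal(st$s_n, 0)
  expect_equal(st$s_m, 0)
  expect_equal(st$E_n, 4)
  expect_equal(st$E_m, 4)
  expect_equal(unname(st$E_c), unname(count_graphlets(g, 4)))
  expect_equal(unname(st$s_c), rep(0, 8))
  # every occupied degree gets its own width-1 bin
  widths <- diff(st$bins$edges)
  expect_true(all(widths[st$bins$weights > 0] == 1))
  expect_error(sample_statistics(make_uncertain_star(5, 0.5), S = 1),
               "at least 2")
})

test_that("the star fixture reproduces the spread-out hub peak", {
  st <- star_target()
  expect_equal(st$E_n, 22, tolerance = 0.02)    # 1 + 30 * 0.7
  # hub peak centered at degree 21
  hub_region <- which(seq_along(st$E_N) >= 10)
  expect_equal(hub_region[which.max(st$E_N[hub_region])], 21)
  # the whole peak lies below the N(k) = 1 line
  expect_true(all(st$E_N[hub_region] < 1))
  # binning collapses it into a single bin of weight exactly one
  peak_bin <- which(st$bins$edges[-length(st$bins$edges)] >= 10 &
                      st$bins$weights > 0)
  expect_length(peak_bin, 1)
  expect_equal(st$bins$weights[peak_bin], 1, tolerance = 1e-9)
  expect_lt(st$bins$s_bin[peak_bin], 1e-6)
  # hub bin accounts for 1/E_n of the distribution
  expect_equal(st$E_p[peak_bin], 1 / st$E_n, tolerance = 1e-9)
})

test_that("mean size of a two-edge path target is one", {
  g <- uncertain_graph(data.frame(from = c("a", "b"), to = c("b", "c"),
                                  prob = 0.5))
  set.seed(8)
  st <- sample_statistics(g, S = 4000, n_g = 3)
  # E(m of largest component) = 0.25*2 + 0.5*1 + 0.25*0 = 1
  expect_equal(st$E_m, 1, tolerance = 0.05)
})

test_that("wide-bin standard deviations bracket floor and ceiling", {
  expect_equal(wide_bin_stdev(1.6), 0.3)
  expect_equal(wide_bin_stdev(2.0), 0)
  expect_equal(wide_bin_stdev(0.25), 0.375)
  expect_error(wide_bin_stdev(-1), "nonnegative")
  # minimality: the interval [w - 2s, w + 2s] just contains both integers
  for (w in c(0.1, 1.2, 3.9)) {
    s <- wide_bin_stdev(w)
    expect_lte(w - 2 * s, floor(w) + 1e-12)
    expect_gte(w + 2 * s, ceiling(w) - 1e-12)
  }
})

test_that("degree binning follows the descending accumulation rule", {
  # two sub-unit entries merge into one bin of weight one
  E_N <- c(1, 0, 0, 0, 0, 0, 0, 0, 0.4, 0.6)
  b <- bin_degrees(E_N, S = 1000)
  i <- findInterval(9, b$edges)
  expect_equal(findInterval(10, b$edges), i)     # 9 and 10 share a bin
  expect_equal(b$weights[i], 1.0)
  # zero run between occupied degrees becomes a dedicated zero bin
  zb <- which(b$zero_bin)
  expect_true(length(zb) >= 1)
  expect_true(all(b$weights[zb] == 0))
  # bins tile the degree range
  expect_equal(b$edges[1], 1)
  expect_equal(b$edges[length(b$edges)], 11)
  expect_error(bin_degrees(rep(0, 5), 100), "empty")
})

test_that("bin weights sum to the mean order and survive more sampling", {
  st <- er_target()
  expect_equal(sum(st$bins$weights), st$E_n, tolerance = 1e-9)
  star <- star_target()
  expect_equal(sum(star$bins$weights), star$E_n, tolerance = 1e-9)

  # stability: bin count unchanged between S = 5000 and S = 10000 (the
  # point of the 1% tail rule)
  set.seed(21)
  st5 <- graip(make_uncertain_star(31, 0.7), S = 5000, n_g = 3)
  expect_equal(length(st5$bins$weights), length(star$bins$weights))
})

test_that("graphlet count moments converge across independent runs", {
  g <- make_uncertain_er(30, 4, rng_seed = 13)
  set.seed(1)
  a <- sample_statistics(g, S = 5000, n_g = 4)
  set.seed(2)
  b <- sample_statistics(g, S = 5000, n_g = 4)
  se <- sqrt(a$s_c^2 / 5000 + b$s_c^2 / 5000) + 1e-9
  expect_true(all(abs(a$E_c - b$E_c) < 4 * se + 1e-6))
})

test_that("binned distribution normalizes and serializes", {
  tri <- igraph::make_graph(~ a - b, b - c, c - a)
  st <- certain_target(tri, S = 5, n_g = 3)
  bd <- binned_distribution(st)
  expect_equal(bd$E_p, 1)        # all mass on the single degree-2 bin
  expect_equal(bd$s_p, 0)
  expect_equal(sum(er_target()$E_p), 1, tolerance = 1e-9)

  f <- withr::local_tempfile(fileext = ".json")
  st2 <- er_target()
  write_target_stats(st2, f)
  back <- read_target_stats(f)
  for (nm in c("E_n", "s_n", "E_m", "s_m", "E_N", "s_N", "E_p", "s_p",
               "E_c", "s_c", "cc_bar", "n_g", "S"))
    expect_equal(back[[nm]], st2[[nm]], tolerance = 1e-12, info = nm)
  expect_equal(back$bins$edges, st2$bins$edges)
})
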