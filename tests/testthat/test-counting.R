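test_that("clique counts follow binomial coefficients", {
  gc <- graphlet_catalog()
  clique_id <- c(`3` = "M2", `4` = "M8", `5` = "M29")
  for (n in 5:7) {
    cnt <- count_graphlets(igraph::make_full_graph(n), 5)
    for (k in 3:5)
      expect_equal(unname(cnt[clique_id[as.character(k)]]), choose(n, k))
    # non-clique types never occur in complete graphs
    expect_equal(sum(cnt[setdiff(names(cnt), clique_id)]), 0)
  }
  expect_equal(unname(count_graphlets(igraph::make_ring(3), 3)),
               c(0, 1))
  expect_equal(unname(count_graphlets(path_graph(3), 3)), c(1, 0))
})

test_that("counts agree with igraph's motif census for orders 3 and 4", {
  # map igraph's isomorphism-class indices onto catalog ids
  iso_map <- function(size) {
    n_cls <- if (size == 3) 4 else 11
    vapply(seq_len(n_cls) - 1, function(cls) {
      g <- igraph::graph_from_isomorphism_class(size, cls, directed = FALSE)
      if (!igraph::is_connected(g)) return(NA_character_)
      classify_subgraph(seq_len(size), g)
    }, "")
  }
  set.seed(3)
  for (i in 1:3) {
    g <- igraph::sample_gnm(40, 100)
    cnt <- count_graphlets(g, 4)
    for (size in 3:4) {
      m <- igraph::motifs(g, size)
      map <- iso_map(size)
      for (cls in which(!is.na(map)))
        expect_equal(unname(cnt[map[cls]]), m[cls],
                     info = paste("size", size, "class", cls))
    }
  }
})

test_that("clustering coefficients match worked examples and igraph", {
  expect_equal(clustering_global(count_graphlets(igraph::make_ring(3), 3)), 1)
  expect_equal(clustering_global(count_graphlets(path_graph(3), 3)), 0)
  k4 <- igraph::make_full_graph(4)
  expect_equal(clustering_global(count_graphlets(k4, 3)), 1)  # T=4, W=0
  expect_equal(clustering_global(c(M1 = 0, M2 = 0)), 0)       # degenerate

  set.seed(4)
  for (i in 1:5) {
    g <- igraph::sample_gnm(30, 70)
    expect_equal(clustering_global(count_graphlets(g, 3)),
                 igraph::transitivity(g, type = "global"))
  }

  star <- igraph::make_star(6, mode = "undirected")
  expect_equal(clustering_local(star, 1), 0)
  expect_equal(clustering_local(igraph::make_ring(3), 2), 1)
  expect_equal(clustering_local(path_graph(2), 1), 0)  # degree-1 convention
  g <- igraph::sample_gnm(25, 60)
  loc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  for (v in sample(25, 8))
    expect_equal(clustering_local(g, v), loc[v])
})

test_that("edge deltas match worked examples", {
  p3 <- igraph::make_graph(~ a - b, b - c)
  d <- delta_for_edge(p3, "a", "c", adding = TRUE, n_g = 3)
  expect_equal(unname(d), c(-1, 1))  # one open triplet becomes a triangle

  iso <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(iso)$name <- letters[1:4]
  expect_equal(sum(abs(delta_for_edge(iso, "a", "b", TRUE, 5))), 0)

  expect_error(delta_for_edge(p3, "a", "b", adding = TRUE), "already present")
  expect_error(delta_for_edge(p3, "a", "c", adding = FALSE), "not present")
})

test_that("node deltas match worked examples", {
  g <- igraph::make_full_graph(4)
  igraph::V(g)$name <- letters[1:4]
  d <- delta_for_node(g, "u", letters[1:4], adding = TRUE, n_g = 5)
  expect_equal(unname(d["M29"]), 1)  # K4 + joined node = one new 5-clique
  expect_equal(unname(d["M8"]), 4)   # and four new 4-cliques

  iso <- igraph::add_vertices(g, 1, name = "z")
  expect_equal(sum(abs(delta_for_node(iso, "z", adding = FALSE, n_g = 5))), 0)
  expect_error(delta_for_node(g, "a", incident_edges = "b", adding = FALSE),
               "must match")
})

test_that("incremental deltas equal full recounts over random edits", {
  # quick randomized oracle (the deeper 200-edit version runs in the
  # acceptance suite)
  set.seed(5)
  for (n_g in 3:5) {
    g <- named_gnm(40, 80)
    c0 <- count_graphlets(g, n_g)
    for (i in 1:15) {
      uv <- sample(igraph::V(g)$name, 2)
      adding <- !igraph::are_adjacent(g, uv[1], uv[2])
      d <- delta_for_edge(g, uv[1], uv[2], adding, n_g)
      g <- if (adding) igraph::add_edges(g, uv) else
        igraph::delete_edges(g, paste0(uv[1], "|", uv[2]))
      c0 <- c0 + d
      expect_equal(unname(c0), unname(count_graphlets(g, n_g)))
    }
    expect_true(all(c0 >= 0))
  }
})

test_that("anchored enumeration yields each connected set exactly once", {
  tri <- igraph::make_graph(~ u - v, v - w, w - u)
  sets <- enumerate_connected_sets(tri, c("u", "v"), 3)
  expect_length(sets, 1)
  expect_setequal(sets[[1]], c("u", "v", "w"))

  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:4))
  sets <- enumerate_connected_sets(star, "hub", 3)
  expect_length(sets, choose(4, 2))  # hub plus any two leaves

  set.seed(6)
  for (i in 1:10) {
    g <- named_gnm(20, 45)
    anchors <- sample(igraph::V(g)$name, sample(1:2, 1))
    sets <- enumerate_connected_sets(g, anchors, 4)
    keys <- vapply(sets, function(s) paste(sort(s), collapse = "|"), "")
    expect_false(anyDuplicated(keys) > 0)
    expect_true(all(vapply(sets, function(s) all(anchors %in% s), TRUE)))
    # each set induces a connected subgraph
    for (s in sets[seq_len(min(10, length(sets)))])
      expect_true(igraph::is_connected(igraph::induced_subgraph(g, s)))
  }
})
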