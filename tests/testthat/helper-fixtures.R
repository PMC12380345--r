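# Shared fixtures built in code. The ER target mirrors the small-network
# study conditions (50 nodes, mean backbone degree 4, edge probabilities
# uniform on (0,1], envelope from 500 sampled worlds, graphlets to order 4).

er_target <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- make_uncertain_er(50, 4, rng_seed = 7)
      set.seed(7)
      cache <<- graip(g, S = 500, n_g = 4)
    }
    cache
  }
})

star_target <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(11)
      cache <<- graip(make_uncertain_star(31, 0.7), S = 10000, n_g = 3)
    }
    cache
  }
})

# envelope of a certain (all probabilities 1) graph: zero spread
certain_target <- function(graph, S = 10, n_g = 4) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  g <- uncertain_graph(data.frame(from = el[, 1], to = el[, 2], prob = 1))
  sample_statistics(g, S = S, n_g = n_g)
}

named_gnm <- function(n, m) {
  g <- igraph::sample_gnm(n, m)
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  g
}

path_graph <- function(k) igraph::make_ring(k, circular = FALSE)
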