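#' Possible-world semantics
#'
#' An uncertain graph represents a distribution over the `2^m` deterministic
#' graphs obtained by keeping or dropping each edge independently.
#' `sample_world()` draws one such possible world; `world_probability()`
#' evaluates the existential probability of a given world, the product of
#' `P(e)` over kept edges times `1 - P(e)` over dropped ones.
#'
#' Per-edge draws are consumed in the stored (sorted) edge order, so a
#' fixed RNG seed gives the same world regardless of input ordering.
#'
#' @param g an [uncertain_graph].
#' @return `sample_world()` returns an undirected [igraph::igraph] graph on
#'   the full node set of `g`.
#' @examples
#' g <- make_uncertain_star(5, 0.5)
#' set.seed(1)
#' w <- sample_world(g)
#' @export
sample_world <- function(g) {
  stopifnot(inherits(g, "uncertain_graph"))
  keep <- runif(nrow(g$edges)) < g$prob
  el <- ug_edge_names(g)[keep, , drop = FALSE]
  igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2]), directed = FALSE,
    vertices = g$nodes)
}

#' @rdname sample_world
#' @param world_edges a 2-column matrix or data frame of node-name pairs,
#'   the edge set of the world (a subset of the backbone edge set).
#' @export
world_probability <- function(g, world_edges) {
  stopifnot(inherits(g, "uncertain_graph"))
  world_edges <- as.matrix(as.data.frame(world_edges))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  backbone_keys <- key(g$nodes[g$edges[, 1]], g$nodes[g$edges[, 2]])
  if (nrow(world_edges) == 0) return(prod(1 - g$prob))
  wk <- key(world_edges[, 1], world_edges[, 2])
  if (anyDuplicated(wk)) stop("duplicate edge in world")
  idx <- match(wk, backbone_keys)
  if (anyNA(idx))
    stop("world contains an edge not in the backbone: ",
         paste(world_edges[which(is.na(idx))[1], ], collapse = "--"))
  inw <- logical(length(g$prob))
  inw[idx] <- TRUE
  prod(g$prob[inw]) * prod(1 - g$prob[!inw])
}

#' Exact per-node degree moments of an uncertain graph
#'
#' The degree of a node in a possible world is a sum of independent
#' Bernoulli variables, one per incident edge, so its mean is the sum of
#' incident edge probabilities and its variance the sum of `P(e)(1 - P(e))`.
#'
#' @param g an [uncertain_graph].
#' @param v a node identifier.
#' @return Named numeric vector with elements `mean` and `variance`.
#' @examples
#' g <- make_uncertain_star(31, 0.7)
#' node_degree_moments(g, "v01")  # hub: mean 21, variance 6.3
#' @export
node_degree_moments <- function(g, v) {
  stopifnot(inherits(g, "uncertain_graph"))
  iv <- match(v, g$nodes)
  if (is.na(iv)) stop("unknown node: ", v)
  inc <- g$edges[, 1] == iv | g$edges[, 2] == iv
  p <- g$prob[inc]
  c(mean = sum(p), variance = sum(p * (1 - p)))
}

#' Largest connected component
#'
#' Induced subgraph on the largest component of an undirected graph. Ties
#' are broken deterministically: the component containing the smallest node
#' name (radix order) wins.
#'
#' @param graph an [igraph::igraph] graph.
#' @return An [igraph::igraph] graph (the empty graph stays empty).
#' @export
largest_connected_component <- function(graph) {
  if (igraph::vcount(graph) == 0) return(graph)
  comp <- igraph::components(graph)
  mx <- max(comp$csize)
  cand <- which(comp$csize == mx)
  if (length(cand) > 1) {
    nm <- igraph::V(graph)$name
    if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(graph)))
    firsts <- vapply(cand, function(ci)
      sort(nm[comp$membership == ci], method = "radix")[1], "")
    cand <- cand[order(firsts, method = "radix")][1]
  }
  igraph::induced_subgraph(graph, which(comp$membership == cand[1]))
}
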