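#' Exact graphlet counts of a deterministic graph
#'
#' Enumerates every connected node set of size 3 to `n_g` exactly once
#' (ESU-style exclusive-neighborhood extension) and classifies each induced
#' subgraph through the bit-string lookup tables. Counts are induced
#' counts: two occurrences are distinct iff they differ in at least one
#' node, and each node set is counted once.
#'
#' @param graph an undirected simple [igraph::igraph] graph.
#' @param n_g maximum graphlet order, 3, 4 or 5.
#' @return Named numeric vector of counts, one per catalog type up to
#'   order `n_g` (length 2, 8 or 29).
#' @examples
#' count_graphlets(igraph::make_full_graph(5), 4)
#' @export
count_graphlets <- function(graph, n_g = 5) {
  stopifnot(n_g %in% 3:5)
  counts <- cpp_count_all(igraph_adj(graph), as.integer(n_g))
  trim_counts(counts, n_g)
}

igraph_adj <- function(graph) {
  lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
}

trim_counts <- function(counts, n_g) {
  nt <- n_graphlet_types(n_g)
  out <- counts[seq_len(nt)]
  names(out) <- graphlet_ids(n_g)
  out
}

#' Clustering coefficients
#'
#' The global clustering coefficient is `3T / (W + 3T)` where `T` is the
#' triangle count (type `M2`) and `W` the count of open connected triplets
#' (type `M1`); it is 0 for triangle-free graphs and defined as 0 when the
#' graph has no connected triplets at all. The local coefficient of node
#' `v` is `2 t_v / (k_v (k_v - 1))` with `t_v` the number of edges between
#' neighbors of `v`; nodes of degree below 2 get 0.
#'
#' @param counts a graphlet count vector as returned by [count_graphlets]
#'   (only the order-3 entries `M1`, `M2` are used).
#' @return A coefficient in `[0, 1]`.
#' @export
clustering_global <- function(counts) {
  W <- unname(counts[1])
  T3 <- unname(counts[2])
  den <- W + 3 * T3
  if (den == 0) 0 else 3 * T3 / den
}

#' @rdname clustering_global
#' @param graph an undirected [igraph::igraph] graph.
#' @param v a node name or index.
#' @export
clustering_local <- function(graph, v) {
  iv <- as.integer(igraph::V(graph)[v])
  if (length(iv) != 1 || is.na(iv)) stop("unknown node: ", v)
  nb <- as.integer(igraph::neighbors(graph, iv))
  k <- length(nb)
  if (k < 2) return(0)
  tv <- igraph::ecount(igraph::induced_subgraph(graph, nb))
  2 * tv / (k * (k - 1))
}

#' Incremental graphlet count updates
#'
#' Signed per-type change in graphlet counts caused by one edit, computed
#' by enumerating only the connected node sets that touch the edit instead
#' of recounting the whole graph. For an edge edit on `(u, v)` the
#' enumeration runs on the graph *with* the edge present (whichever
#' direction the edit goes), over all connected sets of size `<= n_g`
#' containing both endpoints; each set is classified with the `(u, v)` bit
#' set and cleared, and the two classifications are differenced. For a node
#' edit, all connected sets through the node are counted with the node and
#' its incident edges present; instances are only created (addition) or
#' destroyed (removal), never retyped.
#'
#' `counts(after) = counts(before) + delta` holds exactly.
#'
#' @param graph the graph *before* the edit.
#' @param u,v edge endpoints (node names or indices).
#' @param adding `TRUE` for an addition, `FALSE` for a removal.
#' @param n_g maximum graphlet order.
#' @return Named numeric delta vector.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c)
#' delta_for_edge(g, "a", "c", adding = TRUE, n_g = 3)  # M1 -1, M2 +1
#' @export
delta_for_edge <- function(graph, u, v, adding, n_g = 5) {
  stopifnot(n_g %in% 3:5)
  iu <- as.integer(igraph::V(graph)[u])
  iv <- as.integer(igraph::V(graph)[v])
  connected <- igraph::are_adjacent(graph, iu, iv)
  if (adding && connected) stop("edge already present")
  if (!adding && !connected) stop("edge not present")
  gwith <- if (adding) igraph::add_edges(graph, c(iu, iv)) else graph
  d <- cpp_delta_edge(igraph_adj(gwith), iu, iv, as.integer(n_g))
  if (!adding) d <- -d
  trim_counts(d, n_g)
}

#' @rdname delta_for_edge
#' @param incident_edges for a node addition, the neighbors the new node
#'   attaches to; for a removal it defaults to the node's current neighbors
#'   (supplying anything else is an error).
#' @export
delta_for_node <- function(graph, u, incident_edges = NULL, adding, n_g = 5) {
  stopifnot(n_g %in% 3:5)
  if (adding) {
    if (u %in% igraph::V(graph)$name)
      stop("node already present: ", u)
    gwith <- igraph::add_vertices(graph, 1, name = u)
    iu <- igraph::vcount(gwith)
    nb <- as.integer(igraph::V(gwith)[incident_edges])
    if (length(nb)) gwith <- igraph::add_edges(gwith, rbind(iu, nb))
    d <- cpp_delta_node(igraph_adj(gwith), iu, as.integer(n_g))
  } else {
    iu <- as.integer(igraph::V(graph)[u])
    if (length(iu) != 1 || is.na(iu)) stop("unknown node: ", u)
    cur <- igraph::neighbors(graph, iu)$name
    if (!is.null(incident_edges) && !setequal(incident_edges, cur))
      stop("incident_edges must match the node's current edges")
    d <- -cpp_delta_node(igraph_adj(graph), iu, as.integer(n_g))
  }
  trim_counts(d, n_g)
}

#' Enumerate connected node sets through anchors
#'
#' Yields every connected node set of size 3 to `max_order` that contains
#' all anchor nodes, each exactly once. With no anchors, all connected sets
#' of the graph are enumerated. Sets containing the anchors are
#' automatically confined to the relevant neighborhood of the anchors
#' (depth `max_order - |anchors|`), which is what makes incremental
#' counting local.
#'
#' @param graph an undirected [igraph::igraph] graph.
#' @param anchors node names or indices (possibly empty).
#' @param max_order maximum set size (3-5).
#' @return A list of character vectors (or integer vectors for unnamed
#'   graphs), one per node set.
#' @export
enumerate_connected_sets <- function(graph, anchors = NULL, max_order = 5) {
  stopifnot(max_order %in% 3:5)
  ia <- if (length(anchors)) as.integer(igraph::V(graph)[anchors]) else integer(0)
  sets <- cpp_enumerate_sets(igraph_adj(graph), ia, as.integer(max_order))
  nm <- igraph::V(graph)$name
  if (is.null(nm)) sets else lapply(sets, function(s) nm[s])
}
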