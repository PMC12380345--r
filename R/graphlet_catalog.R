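#' The graphlet catalog
#'
#' A graphlet is a small connected induced subgraph shape. There are
#' exactly 29 non-isomorphic connected graphs on 3-5 nodes: 2 of order
#' three, 6 of order four and 21 of order five, labelled `M1` ... `M29`.
#' Types are ordered by (order, edge count ascending, maximum degree
#' descending, canonical bit-string), which anchors `M1` = 3-path,
#' `M2` = triangle, `M3` = 4-star, `M8` = 4-clique, `M9` = 5-star and
#' `M29` = 5-clique.
#'
#' @return A data frame with one row per graphlet type: `id`, `order`,
#'   `edges`, and `canonical_bits`, a representative labelled edge-set
#'   encoding under the pair-to-bit mapping (see [pair_to_bit_position]).
#' @examples
#' gc <- graphlet_catalog()
#' table(gc$order)  # 2, 6, 21
#' @export
graphlet_catalog <- function() {
  if (is.null(.graip_env$catalog)) .graip_env$catalog <- cpp_catalog()
  .graip_env$catalog
}

# number of graphlet types for a maximum order
n_graphlet_types <- function(n_g) {
  stopifnot(n_g %in% 3:5)
  c(2L, 8L, 29L)[n_g - 2L]
}

graphlet_ids <- function(n_g) graphlet_catalog()$id[seq_len(n_graphlet_types(n_g))]

#' Map a labelled node pair to its bit-string position
#'
#' For a subgraph on `order` nodes with 1-based local labels, the pair
#' `(i, j)` with `i < j` maps to bit position `(j-1)(j-2)/2 + (i-1)`; the
#' least significant bit is position zero. Order-5 subgraphs therefore use
#' 10 bits.
#'
#' @param i,j 1-based node labels with `i < j`.
#' @param order subgraph order (3-5); the pair must fit, `j <= order`.
#' @return Integer bit position.
#' @examples
#' pair_to_bit_position(1, 2, 3)  # 0
#' pair_to_bit_position(4, 5, 5)  # 9
#' @export
pair_to_bit_position <- function(i, j, order) {
  stopifnot(order %in% 3:5)
  if (any(i >= j)) stop("need i < j")
  if (any(i < 1) || any(j > order)) stop("pair out of range for this order")
  (j - 1) * (j - 2) / 2 + (i - 1)
}

#' Bit-string lookup tables for graphlet classification
#'
#' For each order 3-5, a table mapping every possible labelled edge-set
#' bit-string (2^3, 2^6 and 2^10 entries) to its graphlet type, or to
#' nothing when the labelled graph is disconnected. Isomorphic labelings
#' map to the same type, so classification of an enumerated subgraph is a
#' single table lookup. Tables are built once per session and cached.
#'
#' @return A named list with elements `"3"`, `"4"`, `"5"`; each is an
#'   integer vector indexed by `bits + 1`, holding the global type index
#'   (1-29) or 0 for disconnected patterns.
#' @export
build_lookup_tables <- function() {
  if (is.null(.graip_env$tables)) {
    .graip_env$tables <- list(`3` = cpp_lookup_table(3L),
                              `4` = cpp_lookup_table(4L),
                              `5` = cpp_lookup_table(5L))
  }
  .graip_env$tables
}

#' Classify a small node set as a graphlet type
#'
#' Assembles the bit-string of the induced subgraph on an ordered node
#' tuple and looks it up. The result is independent of the ordering of the
#' tuple because the tables are closed under isomorphism.
#'
#' @param nodes an ordered vector of 3-5 distinct nodes (names or indices).
#' @param adjacency either an [igraph::igraph] graph or a predicate
#'   `function(u, v)` returning whether the edge is present.
#' @return The type id (e.g. `"M2"`) or `NA` if the induced subgraph is
#'   disconnected.
#' @examples
#' g <- igraph::make_ring(3)
#' classify_subgraph(c(1, 2, 3), g)  # "M2"
#' @export
classify_subgraph <- function(nodes, adjacency) {
  k <- length(nodes)
  if (k < 3 || k > 5) stop("tuple must have 3 to 5 nodes")
  if (anyDuplicated(nodes)) stop("duplicate nodes in tuple")
  test <- if (inherits(adjacency, "igraph")) {
    function(u, v) igraph::are_adjacent(adjacency, u, v)
  } else adjacency
  bits <- 0L
  for (j in 2:k) for (i in 1:(j - 1)) {
    if (isTRUE(test(nodes[i], nodes[j])))
      bits <- bitwOr(bits, bitwShiftL(1L, pair_to_bit_position(i, j, k)))
  }
  t <- cpp_classify_bits(k, bits)
  if (t == 0) NA_character_ else graphlet_catalog()$id[t]
}
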