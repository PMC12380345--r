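#' Uncertain (probabilistic) graphs
#'
#' An uncertain graph is an undirected simple graph in which every edge `e`
#' carries an independent existence probability `P(e)` in `(0, 1]`. It
#' represents a probability distribution over `2^m` deterministic graphs
#' ("possible worlds"); dropping the probabilities gives the *backbone*
#' graph. Typical sources are protein-protein interaction networks whose
#' edges carry confidence scores.
#'
#' Nodes are opaque strings. Internally nodes are stored sorted (radix
#' order) and edges as index pairs `(i, j)`, `i < j`, in lexicographic
#' order; random draws over edges are always consumed in this order, so
#' seeded runs are reproducible regardless of input file ordering.
#'
#' @param edges a data frame or 3-column object with columns `from`, `to`,
#'   `prob`, one row per undirected edge.
#' @param nodes optional character vector of additional (possibly isolated)
#'   node identifiers.
#' @return An object of class `uncertain_graph` with elements `nodes`
#'   (character), `edges` (m x 2 integer matrix of node indices) and `prob`
#'   (numeric).
#' @examples
#' g <- uncertain_graph(data.frame(from = c("a", "b"), to = c("b", "c"),
#'                                 prob = c(0.5, 1)))
#' g
#' @export
uncertain_graph <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 3) stop("need columns from, to, prob")
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  prob <- as.numeric(edges[[3]])
  if (anyNA(prob)) stop("probabilities must be numeric")
  bad <- which(prob <= 0 | prob > 1)
  if (length(bad))
    stop("edge probability out of (0,1] at row ", bad[1], ": ", prob[bad[1]])
  loops <- which(from == to)
  if (length(loops))
    stop("self-loop at row ", loops[1], ": ", from[loops[1]])
  nodes <- sort(unique(c(from, to, nodes)), method = "radix")
  i <- match(from, nodes)
  j <- match(to, nodes)
  sw <- i > j
  tmp <- i[sw]; i[sw] <- j[sw]; j[sw] <- tmp
  key <- paste(i, j)
  if (anyDuplicated(key))
    stop("duplicate edge at row ", which(duplicated(key))[1])
  o <- order(i, j)
  structure(
    list(nodes = nodes, edges = cbind(i = i[o], j = j[o]), prob = prob[o]),
    class = "uncertain_graph")
}

#' @export
print.uncertain_graph <- function(x, ...) {
  cat("Uncertain graph: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges, mean P(e) = ", signif(mean(x$prob), 3), "\n", sep = "")
  invisible(x)
}

#' @rdname uncertain_graph
#' @param g an `uncertain_graph`.
#' @export
backbone <- function(g) {
  stopifnot(inherits(g, "uncertain_graph"))
  el <- cbind(g$nodes[g$edges[, 1]], g$nodes[g$edges[, 2]])
  igraph::graph_from_data_frame(as.data.frame(el), directed = FALSE,
                                vertices = g$nodes)
}

# edge endpoints as a character matrix
ug_edge_names <- function(g) {
  cbind(g$nodes[g$edges[, 1]], g$nodes[g$edges[, 2]])
}

#' Read and write edge lists
#'
#' Probabilistic edge lists are whitespace-separated files with three
#' columns `node_u node_v probability`; deterministic edge lists have two
#' columns. Lines starting with `#` and blank lines are ignored.
#' Probabilities must lie in `(0, 1]`; self-loops and duplicate edges are
#' rejected with an error naming the offending line.
#'
#' @param path file path.
#' @return `read_probabilistic_edgelist()` returns an [uncertain_graph];
#'   `read_edgelist()` returns an undirected [igraph::igraph] graph.
#' @export
read_probabilistic_edgelist <- function(path) {
  toks <- read_token_lines(path, 3)
  prob <- suppressWarnings(as.numeric(toks$f3))
  if (anyNA(prob))
    stop("malformed probability on line ", toks$line[which(is.na(prob))[1]])
  df <- data.frame(from = toks$f1, to = toks$f2, prob = prob)
  tryCatch(uncertain_graph(df), error = function(e) {
    stop(conditionMessage(e), " (line ", toks$line[1], "ff of ", path, ")",
         call. = FALSE)
  })
}

#' @rdname read_probabilistic_edgelist
#' @export
read_edgelist <- function(path) {
  toks <- read_token_lines(path, 2)
  if (length(toks$f1) == 0)
    return(igraph::make_empty_graph(0, directed = FALSE))
  loops <- which(toks$f1 == toks$f2)
  if (length(loops)) stop("self-loop on line ", toks$line[loops[1]])
  nodes <- sort(unique(c(toks$f1, toks$f2)), method = "radix")
  g <- igraph::graph_from_data_frame(
    data.frame(from = toks$f1, to = toks$f2), directed = FALSE,
    vertices = nodes)
  g <- igraph::simplify(g)
  g
}

read_token_lines <- function(path, nfields) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(parts)
  if (any(nf != nfields))
    stop("line ", keep[which(nf != nfields)[1]], ": expected ", nfields,
         " whitespace-separated fields")
  list(f1 = vapply(parts, `[`, "", 1),
       f2 = vapply(parts, `[`, "", 2),
       f3 = if (nfields >= 3) vapply(parts, `[`, "", 3) else NULL,
       line = keep)
}

#' @rdname read_probabilistic_edgelist
#' @param graph an undirected [igraph::igraph] graph.
#' @export
write_edgelist <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  if (nrow(el) == 0) {
    writeLines(character(0), path)
  } else {
    write.table(el, path, quote = FALSE, sep = "\t",
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname read_probabilistic_edgelist
#' @param g an `uncertain_graph`.
#' @export
write_probabilistic_edgelist <- function(g, path) {
  stopifnot(inherits(g, "uncertain_graph"))
  el <- cbind(ug_edge_names(g), sprintf("%.17g", g$prob))
  write.table(el, path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# uniform draw on (0, 1]
runif_left_open <- function(n) 1 - runif(n)

node_names <- function(n) sprintf("v%0*d", nchar(as.character(n)), seq_len(n))

ug_from_igraph <- function(gr, prob) {
  el <- igraph::as_edgelist(gr, names = TRUE)
  uncertain_graph(data.frame(from = el[, 1], to = el[, 2], prob = prob),
                  nodes = igraph::V(gr)$name)
}

#' Synthetic uncertain-graph fixtures
#'
#' Generators for uncertain test networks: a fixed-size Erdos-Renyi
#' `G(n, m)` backbone, a preferential-attachment (Barabasi-Albert style)
#' backbone, and a star. For the random models each backbone edge receives
#' an existence probability drawn uniformly from `(0, 1]`; the star uses a
#' single uniform probability `p`. `G(n, m)` is used (rather than
#' `G(n, p)`) so that the requested average degree is exact.
#'
#' Probabilities are drawn after sorting the edge list, so the same seed
#' yields an identical uncertain graph.
#'
#' @param n number of nodes (`n >= 2`).
#' @param mean_degree average backbone degree; the backbone has
#'   `round(n * mean_degree / 2)` edges.
#' @param rng_seed optional integer seed (`set.seed()` is called when given).
#' @return An [uncertain_graph].
#' @examples
#' g <- make_uncertain_er(50, 4, rng_seed = 1)
#' @export
make_uncertain_er <- function(n, mean_degree, rng_seed = NULL) {
  stopifnot(n >= 2, mean_degree >= 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  m <- round(n * mean_degree / 2)
  m <- min(m, choose(n, 2))
  gr <- igraph::sample_gnm(n, m)
  igraph::V(gr)$name <- node_names(n)
  if (m == 0) {
    return(structure(list(nodes = node_names(n),
                          edges = cbind(i = integer(0), j = integer(0)),
                          prob = numeric(0)),
                     class = "uncertain_graph"))
  }
  ug_from_igraph(gr, prob = rep(1, m)) |> assign_uniform_probs()
}

assign_uniform_probs <- function(g) {
  g$prob <- runif_left_open(nrow(g$edges))
  g
}

#' @rdname make_uncertain_er
#' @export
make_uncertain_ba <- function(n, mean_degree, rng_seed = NULL) {
  stopifnot(n >= 2, mean_degree > 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  m_total <- min(round(n * mean_degree / 2), choose(n, 2))
  quota <- ba_quota(n, m_total)
  gr <- igraph::sample_pa(n, out.seq = quota, directed = FALSE)
  gr <- igraph::simplify(gr)
  igraph::V(gr)$name <- node_names(n)
  ug_from_igraph(gr, prob = rep(1, igraph::ecount(gr))) |>
    assign_uniform_probs()
}

# per-node attachment quotas summing to m_total, each node i (1-based) can
# attach to at most i - 1 earlier nodes
ba_quota <- function(n, m_total) {
  quota <- integer(n)
  base <- m_total %/% (n - 1)
  extra <- m_total %% (n - 1)
  quota[2:n] <- base
  if (extra > 0) quota[n - seq_len(extra) + 1] <- base + 1
  # enforce the attachment cap, pushing overflow to later nodes
  carry <- 0
  for (i in 2:n) {
    q <- quota[i] + carry
    cap <- i - 1
    quota[i] <- min(q, cap)
    carry <- q - quota[i]
  }
  if (carry > 0) for (i in n:2) {
    room <- (i - 1) - quota[i]
    take <- min(room, carry)
    quota[i] <- quota[i] + take
    carry <- carry - take
    if (carry == 0) break
  }
  quota
}

#' @rdname make_uncertain_er
#' @param p uniform edge existence probability in `(0, 1]`.
#' @export
make_uncertain_star <- function(n, p) {
  stopifnot(n >= 2, p > 0, p <= 1)
  nm <- node_names(n)
  uncertain_graph(data.frame(from = nm[1], to = nm[-1], prob = p))
}
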