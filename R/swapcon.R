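#' SwapCon: configuration-model baseline with annealed edge swaps
#'
#' The baseline generator for uncertain targets: (1) draw a degree
#' sequence from the sampled expected degree distribution, (2) build a
#' random graph with that sequence by configuration-model stub matching
#' (projected to a simple graph by discarding self-loops and parallel
#' edges), (3) perform degree-preserving double-edge swaps under simulated
#' annealing until the graphlet counts are close to the expected ones.
#'
#' @param stats a `graip_target` from [graip].
#' @return `degree_sequence_from_stats()` returns an integer vector of
#'   `round(E_n)` degrees with an even sum (one randomly chosen node is
#'   incremented if needed).
#' @export
degree_sequence_from_stats <- function(stats) {
  stopifnot(inherits(stats, "graip_target"))
  n <- round(stats$E_n)
  if (n < 2) stop("degenerate target: mean order below 2")
  b <- stats$bins
  nb <- length(b$weights)
  # representative degree per bin: the sampled-histogram-weighted mean of
  # the degrees inside it (plain midpoint for unobserved zero bins)
  mid <- vapply(seq_len(nb), function(i) {
    ks <- b$edges[i]:(b$edges[i + 1] - 1)
    wk <- stats$E_N[ks]
    if (sum(wk) > 0) as.integer(round(sum(ks * wk) / sum(wk)))
    else as.integer(floor((b$edges[i] + b$edges[i + 1] - 1) / 2))
  }, 1L)
  pr <- stats$E_p
  if (sum(pr) <= 0) stop("empty degree distribution")
  deg <- mid[sample.int(nb, n, replace = TRUE, prob = pr)]
  if (sum(deg) %% 2 == 1) {
    i <- sample.int(n, 1)
    deg[i] <- deg[i] + 1L
  }
  as.integer(deg)
}

#' @rdname degree_sequence_from_stats
#' @param degrees an integer degree sequence with even sum.
#' @return `configuration_graph()` returns a simple undirected
#'   [igraph::igraph] graph whose realized degrees are elementwise at most
#'   the requested ones (stub matchings producing loops or multi-edges are
#'   projected away).
#' @export
configuration_graph <- function(degrees) {
  if (sum(degrees) %% 2 == 1) stop("total degree must be even")
  if (sum(degrees) == 0)
    return(igraph::make_empty_graph(length(degrees), directed = FALSE))
  g <- igraph::sample_degseq(degrees, method = "configuration")
  igraph::simplify(g)
}

#' @rdname degree_sequence_from_stats
#' @param g a simple undirected [igraph::igraph] graph.
#' @param n_g maximum graphlet order (defaults to the target's).
#' @param energy_threshold stop when the energy falls below this (5%).
#' @param temperature initial annealing temperature.
#' @param cooling multiplicative cooling factor, applied per proposal.
#' @param max_stall stop after this many proposals in a row without an
#'   energy-improving swap (default `round(E_m)`). Energy-neutral swaps
#'   are still executed (they randomize the graph) but do not reset the
#'   counter, otherwise plateaus would never terminate.
#' @param max_proposals hard cap on proposals.
#' @param time_cap wall-clock cap in seconds.
#' @return `anneal_swaps()` returns the annealed graph with graph
#'   attributes `energy_initial` and `energy_final`. The energy of a graph
#'   is the mean relative deviation of its graphlet counts from the target
#'   means, `mean(|C_i - E_i| / max(E_i, 1))`.
#' @export
anneal_swaps <- function(g, stats, n_g = stats$n_g, energy_threshold = 0.05,
                         temperature = 0.01, cooling = 0.99,
                         max_stall = NULL, max_proposals = Inf,
                         time_cap = 3600) {
  stopifnot(inherits(stats, "graip_target"), n_g <= stats$n_g)
  if (is.null(max_stall)) max_stall <- max(1, round(stats$E_m))
  nt <- n_graphlet_types(n_g)
  E <- unname(stats$E_c)[seq_len(nt)]
  energy <- function(C) mean(abs(unname(C) - E) / pmax(E, 1))

  el <- igraph::as_edgelist(g, names = FALSE)
  nV <- igraph::vcount(g)
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  cur_E <- energy(cpp_count_all(adj, as.integer(n_g))[seq_len(nt)])
  e0 <- cur_E
  Tt <- temperature
  stall <- 0
  props <- 0
  t_start <- Sys.time()

  swap_adj <- function(adj, a, b, c_, d) {
    # (a,b),(c,d) -> (a,d),(c,b)
    adj[[a]] <- c(adj[[a]][adj[[a]] != b], d)
    adj[[b]] <- c(adj[[b]][adj[[b]] != a], c_)
    adj[[c_]] <- c(adj[[c_]][adj[[c_]] != d], b)
    adj[[d]] <- c(adj[[d]][adj[[d]] != c_], a)
    adj
  }

  while (cur_E >= energy_threshold && stall < max_stall &&
         props < max_proposals &&
         as.numeric(Sys.time() - t_start, units = "secs") < time_cap &&
         nrow(el) >= 2) {
    props <- props + 1
    ij <- sample.int(nrow(el), 2)
    a <- el[ij[1], 1]; b <- el[ij[1], 2]
    c_ <- el[ij[2], 1]; d <- el[ij[2], 2]
    if (runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
    ok <- length(unique(c(a, b, c_, d))) == 4 &&
      !(d %in% adj[[a]]) && !(b %in% adj[[c_]])
    accepted <- FALSE
    if (ok) {
      adj2 <- swap_adj(adj, a, b, c_, d)
      E2 <- energy(cpp_count_all(adj2, as.integer(n_g))[seq_len(nt)])
      dE <- E2 - cur_E
      if (dE < 0 || runif(1) < exp(-dE / Tt)) {
        el[ij[1], ] <- c(a, d)
        el[ij[2], ] <- c(c_, b)
        adj <- adj2
        cur_E <- E2
        accepted <- dE < 0  # neutral swaps keep the graph random but
                            # do not reset the stall counter
      }
    }
    Tt <- Tt * cooling
    stall <- if (accepted) 0 else stall + 1
  }
  out <- igraph::add_edges(igraph::make_empty_graph(nV, directed = FALSE),
                           t(el))
  igraph::V(out)$name <- as.character(seq_len(nV))
  out <- igraph::set_graph_attr(out, "energy_initial", e0)
  out <- igraph::set_graph_attr(out, "energy_final", cur_E)
  out <- igraph::set_graph_attr(out, "proposals", props)
  out
}

#' @rdname degree_sequence_from_stats
#' @param ... passed to [anneal_swaps].
#' @return `swapcon_generate()` chains the three steps and returns the
#'   annealed graph.
#' @export
swapcon_generate <- function(stats, ...) {
  anneal_swaps(configuration_graph(degree_sequence_from_stats(stats)),
               stats, ...)
}
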