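#' Building blocks of the incremental generator
#'
#' `logistic_gate()` maps a standardized deviation `d` to `1/(1 + exp(-d))`;
#' during generation a node (or edge) is *added* when a uniform draw `r`
#' exceeds the gate, so a graph far below its target order is almost
#' certain to grow and one at the target adds or removes with equal
#' probability. `edge_deviation()` is the standardized deviation of the
#' edge count, with `m` scaled by `E_n / n` so that a graph whose order is
#' off target is not additionally pushed toward the wrong density.
#' `p_neighbor()` is the probability with which a newly inserted node,
#' anchored at `v`, also connects to each existing neighbor of `v`; it is
#' chosen so that the expected local clustering coefficient of `v` after
#' the insertion equals the target's mean clustering coefficient, clamped
#' to `[0, 1]`.
#'
#' @param deviation standardized deviation, e.g. `(n - E_n) / s_n`.
#' @return A probability.
#' @examples
#' logistic_gate(0)    # 0.5
#' p_neighbor(2, 0, 0.5)  # 0.75
#' @export
logistic_gate <- function(deviation) 1 / (1 + exp(-deviation))

#' @rdname logistic_gate
#' @param n,m current order and size of the growing graph.
#' @param stats a `graip_target`.
#' @export
edge_deviation <- function(n, m, stats) {
  if (n == 0) stop("empty graph has no edge deviation")
  (m * stats$E_n / n - stats$E_m) / max(stats$s_m, 1e-6)
}

#' @rdname logistic_gate
#' @param k_v degree of the anchor node before the insertion (`>= 1`).
#' @param e_nv number of edges among the neighbors of the anchor.
#' @param cc_bar target mean clustering coefficient.
#' @export
p_neighbor <- function(k_v, e_nv, cc_bar) {
  if (k_v < 1) stop("anchor degree must be at least 1")
  min(max((cc_bar * k_v * (k_v + 1) / 2 - e_nv) / k_v, 0), 1)
}

#' Cost of a candidate graph against the target envelope
#'
#' Two contributions, mixed by weight `w`. The degree term compares
#' *reversed cumulative* binned degree distributions (the fraction of
#' nodes of degree at least the bin's lower edge) by mean relative
#' deviation; the cumulative form avoids penalizing an excess of
#' low-degree nodes matched by a shortage of high-degree ones, which is
#' inevitable while high-degree nodes grow from low-degree ones. The
#' graphlet term is logarithmic: only counts outside `[E - 2s, E + 2s]`
#' contribute, and the log base `1 + f` (above) or `1 - f` (below), with
#' `f = 2s/E`, is the factor by which `E` must be multiplied to reach the
#' bound -- appropriate because dense structures make counts of contained
#' graphlets change multiplicatively (a 10-clique holds 252 5-cliques, a
#' 9-clique only 126).
#'
#' Degenerate guards: cumulative bins with zero target mass are skipped;
#' a zero count below the lower bound enters the log as 0.5 (capped at the
#' target mean); target means of zero are floored at 0.5; log bases are
#' clamped to `[0.01, 1 - 1e-6]` below and `>= 1 + 1e-6` above; each
#' contribution is floored at zero.
#'
#' @param P_binned binned degree distribution of the candidate (fractions,
#'   aligned with the target's bins).
#' @param C graphlet count vector of the candidate.
#' @param stats a `graip_target`.
#' @param w weight of the degree term in `[0, 1]`.
#' @return A list with `cost_p`, `cost_c` and `total`.
#' @export
graip_cost <- function(P_binned, C, stats, w = 2/3) {
  Ep <- stats$E_p
  Pc <- rev(cumsum(rev(P_binned)))
  Epc <- rev(cumsum(rev(Ep)))
  keep <- Epc > 0
  cost_p <- sum(abs(Pc - Epc)[keep] / Epc[keep]) / length(Ep)

  E <- unname(stats$E_c)
  s <- unname(stats$s_c)
  C <- unname(C)
  nE <- length(E)
  Efl <- ifelse(E > 0, E, 0.5)
  f <- 2 * s / Efl
  lo <- E - 2 * s
  hi <- E + 2 * s
  contrib <- numeric(nE)
  below <- C < lo
  above <- C > hi
  if (any(below)) {
    Carg <- ifelse(C[below] == 0, pmin(0.5, Efl[below]), C[below])
    base <- pmin(pmax(1 - f[below], 0.01), 1 - 1e-6)
    contrib[below] <- log(Carg / Efl[below]) / log(base)
  }
  if (any(above)) {
    base <- pmax(1 + f[above], 1 + 1e-6)
    contrib[above] <- log(C[above] / Efl[above]) / log(base)
  }
  cost_c <- sum(pmax(contrib, 0)) / nE
  list(cost_p = cost_p, cost_c = cost_c,
       total = w * cost_p + (1 - w) * cost_c)
}

#' Is a graph inside the target envelope?
#'
#' Elementwise containment (closed intervals) of the graph's *binned*
#' degree distribution in `[E_p - 2 s_p, E_p + 2 s_p]` and of every
#' graphlet count in `[E_c - 2 s_c, E_c + 2 s_c]`. Degrees outside the
#' target's binned range are accumulated into the nearest boundary bin, so
#' such graphs register as out of bounds rather than failing.
#'
#' @param graph an undirected [igraph::igraph] graph.
#' @param stats a `graip_target`.
#' @return Logical.
#' @export
within_bounds <- function(graph, stats) {
  if (igraph::vcount(graph) == 0) return(FALSE)
  deg <- igraph::degree(graph)
  K <- max(deg, 1)
  histN <- tabulate(deg[deg > 0], nbins = K)
  C <- count_graphlets(graph, stats$n_g)
  bounds_check(histN, sum(deg == 0), igraph::vcount(graph), C, stats)
}

bounds_check <- function(histN, n0, n, C, stats, eps = 1e-9) {
  P <- binned_histogram(histN, n0, stats$bins) / n
  all(abs(P - stats$E_p) <= 2 * stats$s_p + eps) &&
    all(abs(unname(C) - unname(stats$E_c)) <= 2 * unname(stats$s_c) + eps)
}

#' Generate a random graph inside a target envelope
#'
#' Grows a deterministic graph incrementally (the GRAIP algorithm): every
#' `node_step`-th step proposes a node insertion or removal, other steps
#' propose an edge insertion or removal; whether to grow or shrink is
#' decided by a logistic gate on the standardized deviation of the order
#' (or scaled size) from its target mean. Each proposal's effect on the
#' graphlet counts is computed incrementally by enumerating only the
#' subgraphs touching the edit -- the temporary graph is never
#' materialized -- and the proposal is accepted when it lowers the cost
#' ([graip_cost]), or unconditionally after `max_rej` consecutive
#' rejections (which keeps the process from stalling near the target).
#' Generation stops the moment the graph lies [within_bounds], or after
#' `max_s` steps.
#'
#' Node insertion follows a preferential-attachment flavored proposal: the
#' anchor neighbor is drawn with probability proportional to degree; if
#' the anchor belongs to a clique of order at least four the new node
#' joins the largest clique containing the anchor (keeping large cliques
#' reachable), otherwise each further neighbor of the anchor is linked
#' with probability [p_neighbor]. The seed graph is a small
#' preferential-attachment graph with `seed_fraction` of the target's
#' nodes and edges.
#'
#' Draw order per step is fixed (gate draw, then proposal draws), so a
#' given seed reproduces the run exactly.
#'
#' @param stats a `graip_target` from [graip].
#' @param max_s step cap (default unlimited: run until within bounds).
#' @param node_step steps between node moves (default 5).
#' @param w cost weight of the degree term (default 2/3).
#' @param max_rej forced-acceptance threshold; `NULL` (default) sets
#'   `max(1, round(0.02 * E_m))`.
#' @param seed_fraction fraction of target nodes/edges in the seed graph.
#' @param n_g maximum graphlet order (defaults to the target's).
#' @param verbose print a progress line every 1000 steps.
#' @param trace record per-step bookkeeping (proposal kind, acceptance,
#'   forced acceptances, rejection streak) in attribute `"trace"`.
#' @return An [igraph::igraph] graph with graph attributes `steps` (number
#'   of iterations used), `within_bounds`, `work` (total subgraph sets
#'   enumerated) and `cost` (final total cost).
#' @examples
#' \donttest{
#' g <- make_uncertain_er(50, 4, rng_seed = 1)
#' fit <- graip(g, S = 500, n_g = 4)
#' h <- graip_generate(fit)
#' igraph::graph_attr(h, "within_bounds")
#' }
#' @export
graip_generate <- function(stats, max_s = Inf, node_step = 5, w = 2/3,
                           max_rej = NULL, seed_fraction = 0.2,
                           n_g = stats$n_g, verbose = FALSE, trace = FALSE) {
  stopifnot(inherits(stats, "graip_target"), node_step >= 1,
            w >= 0, w <= 1, n_g <= stats$n_g)
  if (stats$E_n < 5)
    stop("degenerate target: mean sampled order below 5")
  if (is.null(max_rej)) max_rej <- max(1, round(0.02 * stats$E_m))
  stopifnot(max_rej >= 1)
  nt <- n_graphlet_types(n_g)
  s_n <- max(stats$s_n, 1e-6)

  st <- new_state(seed_graph(stats, seed_fraction), n_g)
  tr <- if (trace) list() else NULL
  step <- 0
  repeat {
    if (bounds_check(st$histN, st$n0, st$n, st$C[seq_len(nt)], stats))
      return(state_to_igraph(st, stats, step, TRUE, w, n_g, tr))
    if (step >= max_s)
      return(state_to_igraph(st, stats, step, FALSE, w, n_g, tr))
    step <- step + 1
    r <- runif(1)
    prop <- if (step %% node_step == 0) {
      if (r > logistic_gate((st$n - stats$E_n) / s_n)) {
        propose_node_add(st, stats$cc_bar, n_g, stats$bins)
      } else propose_node_remove(st, n_g, stats$bins)
    } else {
      if (r > logistic_gate(edge_deviation(st$n, st$m, stats))) {
        propose_edge_add(st, n_g, stats$bins)
      } else propose_edge_remove(st, n_g, stats$bins)
    }
    if (is.null(prop)) next  # degenerate proposal (e.g. nothing to remove)

    cost_H <- graip_cost(binned_histogram(st$histN, st$n0, stats$bins) / st$n,
                         st$C[seq_len(nt)], stats, w)$total
    cost_T <- graip_cost(prop$P_binned, prop$C[seq_len(nt)], stats, w)$total
    improves <- cost_T < cost_H
    forced <- !improves && st$reject_streak >= max_rej
    if (trace)
      tr[[length(tr) + 1]] <- data.frame(
        step = step, kind = prop$kind, accepted = improves || forced,
        forced = forced, streak_before = st$reject_streak,
        cost_H = cost_H, cost_T = cost_T, n = st$n, m = st$m)
    if (improves || forced) {
      apply_proposal(st, prop)
      st$reject_streak <- 0
    } else {
      undo_proposal(st, prop)
      st$reject_streak <- st$reject_streak + 1
    }
    if (verbose && step %% 1000 == 0)
      message(sprintf("step %d: n=%d m=%d cost=%.4f streak=%d",
                      step, st$n, st$m, cost_H, st$reject_streak))
  }
}

# ---- generator state ------------------------------------------------------
# Environment with: adj (list of integer neighbor vectors), alive (logical),
# deg (integer), free (recyclable slots), n (alive count), n0 (alive nodes
# of degree 0), m, histN (histogram over degrees >= 1), C (29 counts),
# reject_streak, work.

new_state <- function(graph, n_g) {
  st <- new.env(parent = emptyenv())
  n <- igraph::vcount(graph)
  st$adj <- lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
  st$alive <- rep(TRUE, n)
  st$deg <- lengths(st$adj)
  st$free <- integer(0)
  st$n <- n
  st$n0 <- sum(st$deg == 0)
  st$m <- sum(st$deg) / 2
  st$histN <- tabulate(st$deg[st$deg > 0], nbins = max(st$deg, 1))
  st$C <- as.numeric(cpp_count_all(st$adj, as.integer(n_g)))
  st$reject_streak <- 0
  st$work <- 0
  st
}

seed_graph <- function(stats, seed_fraction) {
  n0 <- max(2, round(stats$E_n * seed_fraction))
  m0 <- round(stats$E_m * seed_fraction)
  m0 <- min(max(m0, 1), choose(n0, 2))
  ba_m <- max(1, round(stats$E_m / stats$E_n))
  g <- igraph::sample_pa(n0, m = min(ba_m, n0 - 1), directed = FALSE)
  # adjust edge count to exactly the seed fraction
  mc <- igraph::ecount(g)
  if (mc > m0) {
    g <- igraph::delete_edges(g, sample.int(mc, mc - m0))
  } else if (mc < m0) {
    need <- m0 - mc
    tries <- 0
    while (need > 0 && tries < 1e4) {
      uv <- sample.int(n0, 2)
      if (!igraph::are_adjacent(g, uv[1], uv[2])) {
        g <- igraph::add_edges(g, uv)
        need <- need - 1
      }
      tries <- tries + 1
    }
  }
  g
}

state_histN_grow <- function(st, k) {
  if (k > length(st$histN)) st$histN <- c(st$histN, numeric(k - length(st$histN)))
}

hist_add_degree <- function(st, k) {
  if (k == 0) st$n0 <- st$n0 + 1
  else { state_histN_grow(st, k); st$histN[k] <- st$histN[k] + 1 }
}

hist_drop_degree <- function(st, k) {
  if (k == 0) st$n0 <- st$n0 - 1
  else st$histN[k] <- st$histN[k] - 1
}

# candidate histogram after changing a set of node degrees
candidate_hist <- function(st, nodes_old_deg, nodes_new_deg, add_n = 0) {
  histN <- st$histN
  n0 <- st$n0
  grow <- max(c(nodes_new_deg, 0))
  if (grow > length(histN)) histN <- c(histN, numeric(grow - length(histN)))
  for (k in nodes_old_deg) {
    if (k == 0) n0 <- n0 - 1 else histN[k] <- histN[k] - 1
  }
  for (k in nodes_new_deg) {
    if (k == 0) n0 <- n0 + 1 else histN[k] <- histN[k] + 1
  }
  list(histN = histN, n0 = n0, n = st$n + add_n)
}

alive_nodes <- function(st) which(st$alive)

# degree-proportional node draw (uniform if all degrees zero)
draw_anchor <- function(st) {
  av <- alive_nodes(st)
  dg <- st$deg[av]
  if (all(dg == 0)) av[sample.int(length(av), 1)]
  else av[sample.int(length(av), 1, prob = dg)]
}

# ---- proposals ------------------------------------------------------------
# A proposal evaluates the candidate (delta counts, candidate histogram)
# without mutating alive/deg/hist state. Edge/node *insertions* temporarily
# extend `adj` so the delta enumeration sees the edited graph; `undo` /
# `apply` finalize. Removals enumerate on the intact graph.

propose_node_add <- function(st, cc_bar, n_g, bins) {
  v <- draw_anchor(st)
  clique <- cpp_largest_clique_with(st$adj, v, 12L)
  if (length(clique) >= 4) {
    Eu <- clique
  } else if (st$deg[v] == 0) {
    Eu <- v
  } else {
    nb <- st$adj[[v]]
    e_nv <- sum(vapply(nb, function(x) sum(st$adj[[x]] %in% nb), 0L)) / 2
    p <- p_neighbor(st$deg[v], e_nv, cc_bar)
    Eu <- c(v, nb[runif(length(nb)) < p])
  }
  u <- if (length(st$free)) st$free[1] else length(st$adj) + 1L
  if (u > length(st$adj)) st$adj[[u]] <- integer(0)
  st$adj[[u]] <- as.integer(Eu)
  for (x in Eu) st$adj[[x]] <- c(st$adj[[x]], u)
  d <- cpp_delta_node(st$adj, u, as.integer(n_g))
  st$work <- st$work + attr(d, "work")
  cand <- candidate_hist(st, st$deg[Eu], st$deg[Eu] + 1L, add_n = 1)
  hist_insert <- length(Eu)
  if (hist_insert == 0) cand$n0 <- cand$n0 + 1
  else {
    if (hist_insert > length(cand$histN))
      cand$histN <- c(cand$histN, numeric(hist_insert - length(cand$histN)))
    cand$histN[hist_insert] <- cand$histN[hist_insert] + 1
  }
  list(kind = "node_add", u = u, Eu = Eu, delta = as.numeric(d),
       C = st$C + as.numeric(d),
       P_binned = binned_histogram(cand$histN, cand$n0, bins) / cand$n,
       cand = cand)
}

propose_node_remove <- function(st, n_g, bins) {
  if (st$n <= 3) return(NULL)
  av <- alive_nodes(st)
  u <- av[sample.int(length(av), 1)]
  d <- cpp_delta_node(st$adj, u, as.integer(n_g))
  st$work <- st$work + attr(d, "work")
  Eu <- st$adj[[u]]
  cand <- candidate_hist(st, c(st$deg[Eu], st$deg[u]),
                         c(st$deg[Eu] - 1L, 0L), add_n = -1)
  cand$n0 <- cand$n0 - 1  # u leaves entirely (the 0 above was a placeholder)
  list(kind = "node_remove", u = u, Eu = Eu, delta = -as.numeric(d),
       C = st$C - as.numeric(d),
       P_binned = binned_histogram(cand$histN, cand$n0, bins) / cand$n,
       cand = cand)
}

propose_edge_add <- function(st, n_g, bins) {
  av <- alive_nodes(st)
  if (length(av) < 2 || st$m >= choose(st$n, 2)) return(NULL)
  found <- FALSE
  for (t in seq_len(1e4)) {
    uv <- av[sample.int(length(av), 2)]
    if (!(uv[2] %in% st$adj[[uv[1]]])) { found <- TRUE; break }
  }
  if (!found) stop("could not find a non-edge (graph nearly complete)")
  u <- uv[1]; v <- uv[2]
  st$adj[[u]] <- c(st$adj[[u]], v)
  st$adj[[v]] <- c(st$adj[[v]], u)
  d <- cpp_delta_edge(st$adj, u, v, as.integer(n_g))
  st$work <- st$work + attr(d, "work")
  cand <- candidate_hist(st, st$deg[c(u, v)], st$deg[c(u, v)] + 1L)
  list(kind = "edge_add", u = u, v = v, delta = as.numeric(d),
       C = st$C + as.numeric(d),
       P_binned = binned_histogram(cand$histN, cand$n0, bins) / cand$n,
       cand = cand)
}

propose_edge_remove <- function(st, n_g, bins) {
  if (st$m == 0) return(NULL)
  u <- draw_anchor(st)
  nb <- st$adj[[u]]
  v <- nb[sample.int(length(nb), 1)]
  d <- cpp_delta_edge(st$adj, u, v, as.integer(n_g))
  st$work <- st$work + attr(d, "work")
  cand <- candidate_hist(st, st$deg[c(u, v)], st$deg[c(u, v)] - 1L)
  list(kind = "edge_remove", u = u, v = v, delta = -as.numeric(d),
       C = st$C - as.numeric(d),
       P_binned = binned_histogram(cand$histN, cand$n0, bins) / cand$n,
       cand = cand)
}

apply_proposal <- function(st, prop) {
  switch(prop$kind,
    node_add = {
      u <- prop$u
      if (length(st$free) && st$free[1] == u) st$free <- st$free[-1]
      if (u > length(st$alive)) {
        st$alive <- c(st$alive, rep(FALSE, u - length(st$alive)))
        st$deg <- c(st$deg, rep(0L, u - length(st$deg)))
      }
      st$alive[u] <- TRUE
      st$deg[u] <- length(prop$Eu)
      st$deg[prop$Eu] <- st$deg[prop$Eu] + 1L
    },
    node_remove = {
      u <- prop$u
      for (x in prop$Eu) st$adj[[x]] <- st$adj[[x]][st$adj[[x]] != u]
      st$adj[[u]] <- integer(0)
      st$alive[u] <- FALSE
      st$deg[prop$Eu] <- st$deg[prop$Eu] - 1L
      st$deg[u] <- 0L
      st$free <- c(st$free, u)
    },
    edge_add = {
      st$deg[c(prop$u, prop$v)] <- st$deg[c(prop$u, prop$v)] + 1L
    },
    edge_remove = {
      st$adj[[prop$u]] <- st$adj[[prop$u]][st$adj[[prop$u]] != prop$v]
      st$adj[[prop$v]] <- st$adj[[prop$v]][st$adj[[prop$v]] != prop$u]
      st$deg[c(prop$u, prop$v)] <- st$deg[c(prop$u, prop$v)] - 1L
    })
  st$C <- prop$C
  st$histN <- prop$cand$histN
  st$n0 <- prop$cand$n0
  st$n <- prop$cand$n
  st$m <- st$m + switch(prop$kind, node_add = length(prop$Eu),
                        node_remove = -length(prop$Eu),
                        edge_add = 1, edge_remove = -1)
  invisible(st)
}

undo_proposal <- function(st, prop) {
  # insertions temporarily extended adj; removals never touched it
  switch(prop$kind,
    node_add = {
      u <- prop$u
      for (x in prop$Eu) st$adj[[x]] <- st$adj[[x]][st$adj[[x]] != u]
      st$adj[[u]] <- integer(0)
      if (!(u %in% st$free)) st$free <- c(u, st$free)
    },
    edge_add = {
      st$adj[[prop$u]] <- st$adj[[prop$u]][st$adj[[prop$u]] != prop$v]
      st$adj[[prop$v]] <- st$adj[[prop$v]][st$adj[[prop$v]] != prop$u]
    })
  invisible(st)
}

state_to_igraph <- function(st, stats, steps, ok, w, n_g, tr = NULL) {
  av <- alive_nodes(st)
  idx <- integer(length(st$adj))
  idx[av] <- seq_along(av)
  el <- do.call(rbind, lapply(av, function(u) {
    nb <- st$adj[[u]]
    nb <- nb[nb > u]
    if (length(nb)) cbind(idx[u], idx[nb]) else NULL
  }))
  g <- igraph::make_empty_graph(length(av), directed = FALSE)
  if (!is.null(el)) g <- igraph::add_edges(g, t(el))
  igraph::V(g)$name <- as.character(seq_along(av))
  nt <- n_graphlet_types(n_g)
  cost <- graip_cost(binned_histogram(st$histN, st$n0, stats$bins) / st$n,
                     st$C[seq_len(nt)], stats, w)$total
  g <- igraph::set_graph_attr(g, "steps", steps)
  g <- igraph::set_graph_attr(g, "within_bounds", ok)
  g <- igraph::set_graph_attr(g, "work", st$work)
  g <- igraph::set_graph_attr(g, "cost", cost)
  if (!is.null(tr)) attr(g, "trace") <- do.call(rbind, tr)
  g
}

#' Simulate graphs from a fitted target envelope
#'
#' Draws `nsim` graphs from the envelope using the incremental generator
#' ([graip_generate], the default) or the configuration-model baseline
#' ([swapcon_generate]).
#'
#' @param object a `graip_target` from [graip].
#' @param nsim number of graphs.
#' @param seed optional integer seed; the RNG state is restored afterwards
#'   and the seed is attached to the result, following
#'   [stats::simulate()] conventions.
#' @param method `"graip"` or `"swapcon"`.
#' @param ... passed to the generator.
#' @return A list of [igraph::igraph] graphs with attribute `"seed"`.
#' @export
simulate.graip_target <- function(object, nsim = 1, seed = NULL,
                                  method = c("graip", "swapcon"), ...) {
  method <- match.arg(method)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  if (is.null(seed)) {
    rng_state <- get(".Random.seed", envir = globalenv())
  } else {
    rng_old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", rng_old, envir = globalenv()))
    set.seed(seed)
    rng_state <- structure(seed, kind = as.list(RNGkind()))
  }
  out <- replicate(nsim, switch(method,
    graip = graip_generate(object, ...),
    swapcon = swapcon_generate(object, ...)), simplify = FALSE)
  attr(out, "seed") <- rng_state
  out
}
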