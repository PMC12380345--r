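#' Estimate the statistical envelope of an uncertain target network
#'
#' `graip()` is the fitting step of the generator: it Monte-Carlo samples
#' `S` possible worlds of the uncertain graph, takes the largest connected
#' component of each (allowing some variability in the node count), and
#' records the order, size, degree histogram and graphlet counts of every
#' sample. Means `E` and standard deviations `s` of each quantity define
#' the target envelope `[E - 2s, E + 2s]` that generated graphs must fall
#' into. The degree histogram is binned ([bin_degrees]) so that isolated
#' high-degree peaks, whose per-degree mean falls below one node, remain
#' reachable by a deterministic graph.
#'
#' Standard deviations use the population formula (divide by `S`). The
#' average global clustering coefficient of the target is derived from the
#' mean order-3 graphlet counts as `3 E[M2] / (E[M1] + 3 E[M2])`.
#'
#' @param g an [uncertain_graph].
#' @param S number of sampled worlds (at least 2).
#' @param n_g maximum graphlet order taken into account, 3, 4 or 5.
#' @return An object of class `graip_target`: a list with node/edge count
#'   moments (`E_n`, `s_n`, `E_m`, `s_m`), per-degree histogram moments
#'   (`E_N`, `s_N`, degrees 1..max), the binned spec (`bins`), the binned
#'   degree distribution moments (`E_p`, `s_p`), graphlet count moments
#'   (`E_c`, `s_c`), the mean clustering coefficient `cc_bar`, and the
#'   sampling parameters. Use [simulate()][simulate.graip_target] to
#'   generate graphs from it.
#' @examples
#' g <- make_uncertain_star(31, 0.7)
#' set.seed(1)
#' fit <- graip(g, S = 2000, n_g = 3)
#' fit
#' @export
graip <- function(g, S = 10000, n_g = 5) {
  out <- sample_statistics(g, S, n_g)
  out$call <- match.call()
  out
}

#' @rdname graip
#' @export
sample_statistics <- function(g, S, n_g = 5) {
  stopifnot(inherits(g, "uncertain_graph"), n_g %in% 3:5)
  if (S < 2) stop("S must be at least 2 (standard deviations undefined)")
  raw <- cpp_sample_statistics(g$edges, g$prob, length(g$nodes),
                               as.integer(S), as.integer(n_g))
  pop_sd <- function(sum1, sum2) {
    v <- sum2 / S - (sum1 / S)^2
    sqrt(pmax(v, 0))
  }
  nt <- n_graphlet_types(n_g)
  E_N <- raw$sum_N / S
  s_N <- pop_sd(raw$sum_N, raw$sumsq_N)
  E_c <- (raw$sum_C / S)[seq_len(nt)]
  s_c <- pop_sd(raw$sum_C, raw$sumsq_C)[seq_len(nt)]
  names(E_c) <- names(s_c) <- graphlet_ids(n_g)
  bins <- bin_degrees(E_N, S, s_N = s_N)
  E_n <- raw$sum_n / S
  den <- E_c[[1]] + 3 * E_c[[2]]
  obj <- structure(list(
    E_n = E_n, s_n = pop_sd(raw$sum_n, raw$sumsq_n),
    E_m = raw$sum_m / S, s_m = pop_sd(raw$sum_m, raw$sumsq_m),
    E_N = E_N, s_N = s_N, occ_N = raw$occ_N / S,
    bins = bins,
    E_p = bins$weights / E_n,
    s_p = bins$s_bin / E_n,
    E_c = E_c, s_c = s_c,
    cc_bar = if (den > 0) 3 * E_c[[2]] / den else 0,
    n_g = n_g, S = S, n_backbone = length(g$nodes),
    m_backbone = nrow(g$edges)), class = "graip_target")
  obj
}

#' Bin a sampled mean degree histogram
#'
#' Starting from the highest observed degree, consecutive degrees are
#' accumulated into one bin until the bin weight (the summed mean node
#' count) reaches one, so that an isolated high-degree peak -- a hub whose
#' degree is spread out by the sampling -- ends up in a single bin of
#' weight one that a deterministic graph can satisfy. Runs of degrees
#' never observed in any sample get dedicated zero-weight bins. A final
#' adjustment moves tail degrees occurring in less than 1% of samples
#' (mean count below 0.01) from the edge of a peak bin into the adjacent
#' zero bin, so that bin widths do not grow with the number of samples.
#' Only the bin edges move: the (sub-1%) tail mass stays attributed to the
#' peak it belongs to, so an isolated hub peak keeps weight exactly one
#' and `sum(weights)` stays equal to the mean sampled order.
#'
#' @param E_N mean degree histogram, a nonnegative vector indexed by degree
#'   `1..length(E_N)` (degree 0 is excluded: largest components have no
#'   isolated nodes).
#' @param S the number of samples behind `E_N` (the 1% tail rule).
#' @param s_N optional per-degree sampled standard deviations; used as the
#'   bin standard deviation for width-one bins. Wider bins use
#'   [wide_bin_stdev] instead.
#' @return An object of class `graip_bins`: list with `edges` (ascending
#'   integer boundaries, bin `i` covering degrees `[edges[i], edges[i+1])`),
#'   `weights`, `zero_bin` flags and `s_bin`.
#' @export
bin_degrees <- function(E_N, S, s_N = NULL) {
  K <- length(E_N)
  if (K == 0 || all(E_N == 0)) stop("empty degree histogram")
  if (any(E_N < 0)) stop("negative histogram entries")
  edges_desc <- K + 1L
  weights <- numeric(0)
  w <- 0
  zero_bin <- FALSE
  for (be in K:1) {
    w <- w + E_N[be]
    close <- (be == 1L) || (w >= 1) || (zero_bin && E_N[be - 1] != 0)
    if (close) {
      edges_desc <- c(edges_desc, be)
      weights <- c(weights, w)
      w <- 0
      zero_bin <- (be > 1L && E_N[be - 1] == 0)
    }
  }
  edges <- rev(edges_desc)
  weights <- rev(weights)
  zb <- vapply(seq_along(weights), function(i)
    all(E_N[edges[i]:(edges[i + 1] - 1)] == 0), TRUE)

  # tail rule: strip degrees with mean below 0.01 from the boundary of a
  # non-zero bin into the adjacent zero bin
  nb <- length(weights)
  moved <- TRUE
  while (moved) {
    moved <- FALSE
    for (i in seq_len(nb)) {
      if (zb[i]) next
      width <- edges[i + 1] - edges[i]
      if (width <= 1) next
      if (i > 1 && zb[i - 1] && E_N[edges[i]] < 0.01) {
        edges[i] <- edges[i] + 1L
        moved <- TRUE
        break
      }
      if (i < nb && zb[i + 1] && E_N[edges[i + 1] - 1] < 0.01) {
        edges[i + 1] <- edges[i + 1] - 1L
        moved <- TRUE
        break
      }
    }
  }

  # drop leading zero bins below the lowest observed degree: bins tile the
  # observed degree range (a tail-augmented zero bin is kept)
  while (length(weights) > 1 && weights[1] == 0 &&
         all(E_N[edges[1]:(edges[2] - 1)] == 0)) {
    weights <- weights[-1]
    edges <- edges[-1]
    zb <- zb[-1]
  }
  nb <- length(weights)

  s_bin <- vapply(seq_len(nb), function(i) {
    width <- edges[i + 1] - edges[i]
    if (width == 1 && !is.null(s_N)) s_N[edges[i]] else wide_bin_stdev(weights[i])
  }, 0)
  structure(list(edges = as.integer(edges), weights = weights,
                 zero_bin = zb, s_bin = s_bin), class = "graip_bins")
}

#' @export
print.graip_bins <- function(x, ...) {
  nb <- length(x$weights)
  cat("Degree bins (", nb, "):\n", sep = "")
  for (i in seq_len(nb)) {
    cat(sprintf("  [%d, %d)  weight %.4g  s %.4g%s\n", x$edges[i],
                x$edges[i + 1], x$weights[i], x$s_bin[i],
                if (x$zero_bin[i]) "  (zero bin)" else ""))
  }
  invisible(x)
}

#' Standard deviation assigned to a wide degree bin
#'
#' For bins wider than one degree the per-degree sampled deviations are no
#' longer meaningful (the uncertainty has been translated into the bin
#' width). Instead the bin's deviation is the minimal `s` such that the
#' interval `[weight - 2s, weight + 2s]` contains both `floor(weight)` and
#' `ceiling(weight)` -- the number of nodes of a deterministic graph
#' falling into the bin must be an integer, while the weight need not be.
#'
#' @param weight nonnegative bin weight.
#' @return `max(weight - floor(weight), ceiling(weight) - weight) / 2`;
#'   zero for integer weights.
#' @examples
#' wide_bin_stdev(1.6)  # 0.3
#' @export
wide_bin_stdev <- function(weight) {
  if (any(weight < 0)) stop("weight must be nonnegative")
  # tolerate floating error around integer weights (sums of counts / S)
  fl <- floor(weight + 1e-9)
  ce <- ceiling(weight - 1e-9)
  pmax(weight - fl, ce - weight) / 2
}

#' Binned degree distribution of the target
#'
#' Converts the binned mean histogram into distribution form: bin weights
#' divided by the mean sampled order `E_n`, and likewise for the bin
#' standard deviations.
#'
#' @param stats a `graip_target` object.
#' @return A list with `E_p` and `s_p` (both summing/scaling by `E_n`).
#' @export
binned_distribution <- function(stats) {
  stopifnot(inherits(stats, "graip_target"))
  if (stats$E_n == 0) stop("degenerate target: E_n is zero")
  list(E_p = stats$bins$weights / stats$E_n,
       s_p = stats$bins$s_bin / stats$E_n)
}

# map a degree histogram (vector over degrees 1..length, plus n0 nodes of
# degree zero) onto the target's bins; out-of-range degrees accumulate into
# the nearest boundary bin
binned_histogram <- function(histN, n0, bins) {
  nb <- length(bins$weights)
  out <- numeric(nb)
  if (n0 > 0) out[1] <- n0
  ks <- which(histN > 0)
  if (length(ks)) {
    idx <- findInterval(ks, bins$edges)
    idx[idx < 1] <- 1L
    idx[idx > nb] <- nb
    for (t in seq_along(ks)) out[idx[t]] <- out[idx[t]] + histN[ks[t]]
  }
  out
}

#' @export
print.graip_target <- function(x, ...) {
  cat("GRAIP target envelope (", x$S, " sampled worlds, graphlets up to order ",
      x$n_g, ")\n", sep = "")
  cat(sprintf("  order n: %.2f (sd %.2f)   size m: %.2f (sd %.2f)\n",
              x$E_n, x$s_n, x$E_m, x$s_m))
  cat(sprintf("  degree bins: %d   mean clustering: %.4f\n",
              length(x$bins$weights), x$cc_bar))
  cat("  graphlet count means:\n")
  print(signif(x$E_c, 4))
  invisible(x)
}

#' @export
summary.graip_target <- function(object, ...) {
  b <- object$bins
  df <- data.frame(
    bin = sprintf("[%d,%d)", b$edges[-length(b$edges)], b$edges[-1]),
    weight = b$weights, s = b$s_bin, zero_bin = b$zero_bin)
  out <- list(target = object, bins = df,
              graphlets = data.frame(id = names(object$E_c),
                                     E = unname(object$E_c),
                                     s = unname(object$s_c)))
  class(out) <- "summary.graip_target"
  out
}

#' @export
print.summary.graip_target <- function(x, ...) {
  print(x$target)
  cat("\nDegree bins:\n")
  print(x$bins, row.names = FALSE)
  cat("\nGraphlet envelope [E - 2s, E + 2s]:\n")
  gl <- transform(x$graphlets, lower = pmax(E - 2 * s, 0), upper = E + 2 * s)
  print(gl, row.names = FALSE)
  invisible(x)
}

#' @export
#' @importFrom graphics segments points abline legend
plot.graip_target <- function(x, ...) {
  K <- length(x$E_N)
  k <- seq_len(K)
  lo <- pmax(x$E_N - 2 * x$s_N, 0)
  hi <- x$E_N + 2 * x$s_N
  plot(k, x$E_N, pch = 16, cex = 0.6, xlab = "degree k",
       ylab = "mean node count E_N(k)", ylim = c(0, max(hi, 1.05)), ...)
  segments(k, lo, k, hi, col = "darkseagreen3")
  points(k, x$E_N, pch = 16, cex = 0.6)
  abline(h = 1, lty = 2, col = "grey40")
  abline(v = x$bins$edges - 0.5, col = "grey70", lty = 3)
  invisible(x)
}

#' Cache target statistics on disk
#'
#' Sampling is the expensive step and only has to be run once per target;
#' these helpers serialize a `graip_target` to human-readable JSON.
#'
#' @param stats a `graip_target`.
#' @param path file path.
#' @export
write_target_stats <- function(stats, path) {
  stopifnot(inherits(stats, "graip_target"))
  x <- unclass(stats)
  x$call <- NULL
  x$bins <- unclass(x$bins)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_target_stats
#' @export
read_target_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$bins <- structure(x$bins, class = "graip_bins")
  x$bins$edges <- as.integer(x$bins$edges)
  for (nm in c("E_c", "s_c")) x[[nm]] <- setNames(as.numeric(x[[nm]]), names(x[[nm]]))
  names(x$E_c) <- names(x$s_c) <- graphlet_ids(x$n_g)
  structure(x, class = "graip_target")
}
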