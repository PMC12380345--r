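#' Maximum mean discrepancy between graph ensembles
#'
#' Kernel two-sample statistics for comparing a set of generated graphs
#' against a set of graphs sampled from the target. `gaussian_kernel()` is
#' `exp(-||x - y||^2 / (2 sigma^2))`; `mmd_squared()` is the unbiased
#' estimator of the squared maximum mean discrepancy (it can be slightly
#' negative), which is minimal when the two ensembles follow the same
#' distribution.
#'
#' The bandwidth defaults to the median pairwise Euclidean distance over
#' the pooled vectors (median heuristic); absolute values therefore depend
#' on the bandwidth choice and only comparisons under the same bandwidth
#' are meaningful.
#'
#' @param x,y numeric statistic vectors of equal length.
#' @param sigma kernel bandwidth (`> 0`).
#' @return `gaussian_kernel()` returns a scalar in `(0, 1]`.
#' @examples
#' gaussian_kernel(c(0, 0), c(1, 1), sigma = 1)
#' @export
gaussian_kernel <- function(x, y, sigma) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (sigma <= 0) stop("sigma must be positive")
  exp(-sum((x - y)^2) / (2 * sigma^2))
}

#' @rdname gaussian_kernel
#' @param X,Y matrices of statistic vectors, one row per graph (at least
#'   two rows each), with equal column counts.
#' @export
mmd_squared <- function(X, Y, sigma = NULL) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  nx <- nrow(X)
  ny <- nrow(Y)
  if (nx < 2 || ny < 2) stop("need at least two vectors per ensemble")
  if (ncol(X) != ncol(Y)) stop("ensembles must have equal vector length")
  if (is.null(sigma)) sigma <- median_bandwidth(rbind(X, Y))
  K <- kernel_matrix(rbind(X, Y), sigma)
  mmd_from_kernel(K, nx, ny)
}

median_bandwidth <- function(M) {
  d <- as.numeric(dist(M))
  s <- median(d[d > 0])
  if (!is.finite(s) || s <= 0) 1 else s
}

kernel_matrix <- function(M, sigma) {
  D2 <- as.matrix(dist(M))^2
  exp(-D2 / (2 * sigma^2))
}

mmd_from_kernel <- function(K, nx, ny) {
  ix <- seq_len(nx)
  iy <- nx + seq_len(ny)
  Kxx <- K[ix, ix]
  Kyy <- K[iy, iy]
  Kxy <- K[ix, iy]
  (sum(Kxx) - nx) / (nx * (nx - 1)) +
    (sum(Kyy) - ny) / (ny * (ny - 1)) -
    2 * sum(Kxy) / (nx * ny)
}

#' @rdname gaussian_kernel
#' @param n_perm number of label permutations for the null distribution.
#' @param prob quantile of the permutation null to return.
#' @return `mmd_null_quantile()` returns a list with the observed `mmd2`
#'   and the permutation-null quantile `null_q`, both computed under one
#'   shared bandwidth.
#' @export
mmd_null_quantile <- function(X, Y, n_perm = 200, prob = 0.95, sigma = NULL) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  nx <- nrow(X)
  ny <- nrow(Y)
  pooled <- rbind(X, Y)
  if (is.null(sigma)) sigma <- median_bandwidth(pooled)
  K <- kernel_matrix(pooled, sigma)
  obs <- mmd_from_kernel(K, nx, ny)
  null <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(nx + ny)
    mmd_from_kernel(K[p, p], nx, ny)
  }, 0)
  list(mmd2 = obs, null_q = unname(quantile(null, prob, type = 5)))
}

#' Statistic vectors of a graph ensemble
#'
#' Converts each graph to the vector its MMD comparison uses: either the
#' normalized degree histogram (padded with zeros to the maximum degree
#' observed anywhere in the ensemble) or the graphlet count vector (raw
#' counts by default).
#'
#' @param graphs a list of [igraph::igraph] graphs.
#' @param kind `"degree"` or `"graphlets"`.
#' @param n_g maximum graphlet order for `kind = "graphlets"`.
#' @param normalize for `kind = "graphlets"`, divide each count vector by
#'   its total (zero vectors stay zero).
#' @return A numeric matrix, one row per graph.
#' @export
graph_statistic_vectors <- function(graphs, kind = c("degree", "graphlets"),
                                    n_g = 4, normalize = FALSE) {
  kind <- match.arg(kind)
  if (kind == "degree") {
    degs <- lapply(graphs, igraph::degree)
    kmax <- max(vapply(degs, function(d) if (length(d)) max(d) else 0, 0))
    t(vapply(degs, function(d) {
      tabulate(d + 1, nbins = kmax + 1) / max(length(d), 1)
    }, numeric(kmax + 1)))
  } else {
    M <- t(vapply(graphs, function(g) unname(count_graphlets(g, n_g)),
                  numeric(n_graphlet_types(n_g))))
    if (normalize) {
      tot <- rowSums(M)
      M[tot > 0, ] <- M[tot > 0, , drop = FALSE] / tot[tot > 0]
    }
    M
  }
}

#' Randomness spread ratio between ensembles
#'
#' For a graph property not directly controlled by the generator (the
#' diameter of the largest component, or the mean local clustering
#' coefficient), the spread of an ensemble is the difference between its
#' 95th and 5th percentiles. The ratio of generated spread to sampled
#' spread measures how much variety the generator produces relative to the
#' target's own sampling variability: above one means more variety, below
#' one less. Percentiles are computed with piecewise-linear interpolation
#' through the order-statistic midpoints (`quantile(type = 5)`).
#'
#' @param generated,sampled lists of [igraph::igraph] graphs (at least 20
#'   each).
#' @param property `"diameter"` or `"mean_local_cc"`.
#' @return The spread ratio, or `NA` when the sampled spread is zero
#'   (undefined ratio).
#' @export
spread_ratio <- function(generated, sampled,
                         property = c("diameter", "mean_local_cc")) {
  property <- match.arg(property)
  if (length(generated) < 20 || length(sampled) < 20)
    stop("need at least 20 graphs per ensemble")
  f <- switch(property, diameter = graph_diameter, mean_local_cc = mean_local_cc)
  spread <- function(v) {
    q <- quantile(v, c(0.05, 0.95), type = 5, names = FALSE)
    q[2] - q[1]
  }
  sg <- spread(vapply(generated, f, 0))
  ss <- spread(vapply(sampled, f, 0))
  if (ss == 0) {
    warning("sampled ensemble has zero spread; ratio undefined")
    return(NA_real_)
  }
  sg / ss
}

graph_diameter <- function(g) {
  igraph::diameter(largest_connected_component(g), unconnected = FALSE)
}

mean_local_cc <- function(g) {
  if (igraph::vcount(g) == 0) return(0)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  mean(cc)
}
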