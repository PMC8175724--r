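## Network statistics used to compare trained models, random baselines and
## real connectomes: inter-run stability (RMSE on ordered weights),
## cumulative node-strength distributions, and maximum-cluster-size curves
## over strength-thresholded subnetworks.

#' Node strength
#'
#' The sum of absolute connected weights per node, \eqn{s_i = \sum_j
#' |w_{ij}|} -- the weighted analogue of degree, and numerically identical
#' to [wiring_cost()]; kept as a named alias in the metrics vocabulary.
#'
#' @inheritParams propagate
#' @return Nonnegative numeric vector of length `N`.
#' @export
node_strength <- function(W) {
  wiring_cost(W)
}

#' Cumulative node-strength distribution
#'
#' Orders the strengths descending, samples `n_points` quantiles at the
#' ranks nearest \eqn{((n+1)/(m+1)) N} for `n = 0, ..., m-1` (with `m` the
#' number of points), normalizes by the maximum strength, and pairs each
#' point with its cumulative probability \eqn{(n+1)/(m+1)}. When the input
#' has fewer values than `n_points`, every value is used (as done for small
#' networks such as a 65-region cat connectome).
#'
#' @param values Nonnegative numeric vector of node strengths (or any
#'   nonnegative statistic); typically [node_strength()] output, possibly
#'   pooled over repeated runs.
#' @param n_points Number of quantile points to sample (default 100).
#' @return Object of class `strength_distribution`: a data frame with
#'   columns `probability` (cumulative, increasing) and `strength`
#'   (max-normalized, nonincreasing).
#' @export
strength_distribution <- function(values, n_points = 100) {
  if (!is.numeric(values) || length(values) == 0)
    stop("`values` must be a nonempty numeric vector", call. = FALSE)
  if (any(values < 0) || any(!is.finite(values)))
    stop("`values` must be finite and nonnegative", call. = FALSE)
  if (all(values == 0))
    stop("degenerate distribution: all strengths are zero", call. = FALSE)
  N <- length(values)
  m <- min(as.integer(n_points), N)
  s <- sort(values, decreasing = TRUE)
  prob <- (seq_len(m)) / (m + 1)
  rank <- pmin(pmax(round(prob * N), 1L), N)
  out <- data.frame(probability = prob, strength = s[rank] / s[1])
  class(out) <- c("strength_distribution", "data.frame")
  out
}

#' Inter-run stability RMSE
#'
#' Measures how similar independently trained networks are, ignoring node
#' identity: each network's weights are flattened, taken in absolute value,
#' sorted descending and normalized by their mean; the RMSE between the
#' ordered vectors is then averaged over all unordered pairs. Identical or
#' permuted networks give 0; the statistic is also invariant to a global
#' rescaling of any network.
#'
#' @param networks List of >= 2 square weight matrices of identical shape.
#' @return Nonnegative scalar, the pair-averaged RMSE.
#' @export
stability_rmse <- function(networks) {
  if (!is.list(networks) || length(networks) < 2)
    stop("`networks` must be a list of at least two weight matrices",
         call. = FALSE)
  dims <- vapply(networks, function(w) dim(check_weights(w)), integer(2))
  for (k in seq_along(networks)[-1])
    if (!all(dims[, k] == dims[, 1]))
      stop(sprintf("shape mismatch between networks 1 (%dx%d) and %d (%dx%d)",
                   dims[1, 1], dims[2, 1], k, dims[1, k], dims[2, k]),
           call. = FALSE)
  ordered <- lapply(networks, function(w) {
    v <- sort(abs(as.vector(w)), decreasing = TRUE)
    v / mean(v)
  })
  n <- length(ordered)
  pairs <- utils::combn(n, 2)
  rmse <- apply(pairs, 2, function(p)
    sqrt(mean((ordered[[p[1]]] - ordered[[p[2]]])^2)))
  mean(rmse)
}

## Off-diagonal nonzero arcs ordered by decreasing |w|, ties broken by
## (row, column) index so subnetwork selection is deterministic.
ordered_arcs <- function(W) {
  N <- nrow(W)
  ij <- which(W != 0 & !diag(TRUE, N), arr.ind = TRUE)
  if (nrow(ij) == 0)
    return(ij)
  w <- abs(W[ij])
  ij[order(-w, ij[, 1], ij[, 2]), , drop = FALSE]
}

#' Maximum cluster size of a thresholded subnetwork
#'
#' Keeps the top `floor(r * n_c)` connections by absolute weight, where
#' `n_c` is the number of nonzero off-diagonal weights, and returns the
#' largest hub-neighborhood: the maximum over nodes of the number of
#' distinct partners connected to that node in either direction. Ties at
#' the selection boundary are broken by (row, column) index. Diagonal
#' entries never count.
#'
#' @inheritParams propagate
#' @param r Connection ratio in `(0, 1]`.
#' @return Nonnegative integer; 0 when `r * n_c < 1`.
#' @export
max_cluster_size <- function(W, r) {
  check_weights(W)
  if (!is.numeric(r) || length(r) != 1 || r <= 0 || r > 1)
    stop("`r` must lie in (0, 1]", call. = FALSE)
  arcs <- ordered_arcs(W)
  k <- floor(r * nrow(arcs))
  if (k < 1) return(0L)
  top <- arcs[seq_len(k), , drop = FALSE]
  key <- pmin(top[, 1], top[, 2]) + nrow(W) * (pmax(top[, 1], top[, 2]) - 1)
  und <- top[!duplicated(key), , drop = FALSE]
  max(tabulate(c(und[, 1], und[, 2]), nbins = nrow(W)))
}

#' Maximum-cluster-size curve over connection ratios
#'
#' Evaluates [max_cluster_size()] on the grid `r = r_step, 2 r_step, ...,
#' 1` and normalizes by the full-network (`r = 1`) value, so curves from
#' networks of different size are comparable. Computed incrementally by
#' inserting connections in decreasing strength order, so the whole curve
#' costs one pass over the arcs.
#'
#' @inheritParams propagate
#' @param r_step Grid spacing of the connection ratio (default 0.01).
#' @return Object of class `cluster_curve`: data frame with columns
#'   `ratio` and `size` (normalized, nondecreasing, ending at 1).
#' @export
cluster_curve <- function(W, r_step = 0.01) {
  check_weights(W)
  if (!is.numeric(r_step) || length(r_step) != 1 || r_step <= 0 || r_step > 1)
    stop("`r_step` must lie in (0, 1]", call. = FALSE)
  N <- nrow(W)
  arcs <- ordered_arcs(W)
  n_c <- nrow(arcs)
  rgrid <- seq(r_step, 1, by = r_step)
  if (rgrid[length(rgrid)] < 1) rgrid <- c(rgrid, 1)
  if (n_c == 0)
    return(structure(data.frame(ratio = rgrid, size = 0),
                     class = c("cluster_curve", "data.frame")))
  cutoffs <- floor(rgrid * n_c)
  seen <- logical(N * N)
  deg <- integer(N)
  maxdeg <- 0L
  maxdeg_after <- integer(n_c)  # running max degree after inserting arc e
  for (e in seq_len(n_c)) {
    i <- arcs[e, 1]; j <- arcs[e, 2]
    key <- min(i, j) + N * (max(i, j) - 1L)
    if (!seen[key]) {
      seen[key] <- TRUE
      deg[i] <- deg[i] + 1L
      deg[j] <- deg[j] + 1L
      m <- max(deg[i], deg[j])
      if (m > maxdeg) maxdeg <- m
    }
    maxdeg_after[e] <- maxdeg
  }
  sizes <- ifelse(cutoffs >= 1, maxdeg_after[pmax(cutoffs, 1)], 0L)
  full <- sizes[length(sizes)]
  out <- data.frame(ratio = rgrid, size = if (full > 0) sizes / full else 0)
  class(out) <- c("cluster_curve", "data.frame")
  out
}

#' Degree-product weighting of a binary network
#'
#' Converts a binary topological network into a weighted one by assigning
#' each existing connection the product of its endpoint degrees,
#' \eqn{w(i,j) = d(i) d(j)}, where the degree counts distinct partners in
#' either direction (diagonal excluded). This lets strength-based
#' procedures run on purely topological connectomes.
#'
#' @param A Square binary matrix (entries 0/1).
#' @return Weighted numeric matrix of the same shape.
#' @export
degree_product_weights <- function(A) {
  check_weights(A)
  if (!all(A %in% c(0, 1)))
    stop("input is not binary; use the raw weights directly instead",
         call. = FALSE)
  N <- nrow(A)
  und <- (A > 0 | t(A) > 0)
  diag(und) <- FALSE
  d <- rowSums(und)
  W <- outer(d, d)
  W[A == 0] <- 0
  diag(W) <- 0
  W
}
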