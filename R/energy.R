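#' @keywords internal
"_PACKAGE"

## Internal validators shared across the package. Weight matrices are plain
## numeric matrices; signal batches are B x N matrices with entries in
## {-1, 0, +1}. Keeping the containers base-R keeps the hot paths allocation
## free and BLAS friendly.

check_weights <- function(W, arg = "W") {
  if (!is.matrix(W) || !is.numeric(W))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (nrow(W) != ncol(W))
    stop(sprintf("`%s` must be square, got %d x %d", arg, nrow(W), ncol(W)),
         call. = FALSE)
  if (!all(is.finite(W)))
    stop(sprintf("`%s` contains non-finite entries", arg), call. = FALSE)
  invisible(W)
}

check_signals <- function(V0, arg = "V0") {
  if (!is.matrix(V0) || !is.numeric(V0))
    stop(sprintf("`%s` must be a numeric matrix (one signal per row)", arg),
         call. = FALSE)
  if (!all(V0 %in% c(-1, 0, 1)))
    stop(sprintf("`%s` entries must all be -1, 0 or +1", arg), call. = FALSE)
  invisible(V0)
}

check_dims <- function(W, V0) {
  if (ncol(W) != ncol(V0))
    stop(sprintf("dimension mismatch: weight matrix is %d x %d but signals have %d nodes",
                 nrow(W), ncol(W), ncol(V0)), call. = FALSE)
  invisible(NULL)
}

#' Propagate input signals through the network
#'
#' Applies the one-step linear state transition \eqn{v_i = \sum_j w_{ij}
#' v^0_j} to every signal in a batch. Rows of `V0` are input state vectors
#' over the `N` nodes; the returned matrix holds the corresponding
#' post-transition states.
#'
#' @param W Square numeric weight matrix (`N x N`). Entry `W[i, j]` is the
#'   signed connection strength from node `j` into node `i`.
#' @param V0 Numeric matrix of input signals, one per row (`B x N`), entries
#'   in `{-1, 0, 1}`.
#' @return A `B x N` numeric matrix `V` with `V[b, i] = sum_j W[i, j] *
#'   V0[b, j]`.
#' @examples
#' W <- matrix(c(0, 2, -1, 0), 2, 2, byrow = TRUE)
#' propagate(W, matrix(c(1, 1), 1))
#' @export
propagate <- function(W, V0) {
  check_weights(W)
  check_signals(V0)
  check_dims(W, V0)
  V0 %*% t(W)
}

#' Per-node wiring cost
#'
#' The energy expended to build and maintain a node's connections, measured
#' as its total absolute connection strength \eqn{E_w(i) = \sum_j |w_{ij}|}
#' (equivalently, the node strength of the weighted graph).
#'
#' @inheritParams propagate
#' @return Nonnegative numeric vector of length `N`.
#' @export
wiring_cost <- function(W) {
  check_weights(W)
  rowSums(abs(W))
}

#' Per-node activity cost
#'
#' The energy of signal transfer through each node, summing
#' \eqn{|v_i w_{ij} v_j|} over partners `j` under the propagated activation
#' state and averaging over the signals in the batch. With
#' `form = "post_post"` both activation factors are taken from the
#' propagated state `V = W V0` (the default); with `form = "post_pre"` the
#' partner activation `v_j` is the pre-transition input `v0_j`.
#'
#' Because every factor enters in absolute value, the cost factorizes as
#' \eqn{E_a(i) = mean_b |v_{bi}| \sum_j |w_{ij}| |x_{bj}|}, which is how it
#' is computed.
#'
#' @inheritParams propagate
#' @param form Which activation state multiplies the partner side of each
#'   term; `"post_post"` (default) or `"post_pre"`.
#' @return Nonnegative numeric vector of length `N` (batch mean).
#' @export
activity_cost <- function(W, V0, form = c("post_post", "post_pre")) {
  form <- match.arg(form)
  check_weights(W)
  check_signals(V0)
  check_dims(W, V0)
  V <- V0 %*% t(W)
  X <- if (form == "post_post") abs(V) else abs(V0)
  ## (X %*% t(|W|))[b, i] = sum_j |w_ij| x_bj
  colMeans(abs(V) * (X %*% t(abs(W))))
}

#' Normalized energy breakdown of a network state
#'
#' Computes the wiring cost, the batch-averaged activity cost, their
#' per-node ratio \eqn{E_a(i)/E_w(i)}, and the node-averaged ratio that the
#' refinement loop minimizes. Nodes whose wiring cost is exactly zero (a
#' fully disconnected row, possible only after aggressive clipping) are
#' excluded from the mean and reported with a warning.
#'
#' @inheritParams activity_cost
#' @return An object of class `energy_breakdown`: a list with fields
#'   `wiring`, `activity`, `ratio` (length-`N` vectors), `mean_ratio`
#'   (scalar), and `zero_wiring` (integer indices of excluded nodes).
#' @export
normalized_energy <- function(W, V0, form = c("post_post", "post_pre")) {
  form <- match.arg(form)
  wiring <- wiring_cost(W)
  activity <- activity_cost(W, V0, form = form)
  zero <- which(wiring == 0)
  ratio <- ifelse(wiring > 0, activity / wiring, NA_real_)
  if (length(zero) > 0)
    warning(sprintf("%d node(s) with zero wiring cost excluded from mean_ratio",
                    length(zero)), call. = FALSE)
  active <- wiring > 0
  mean_ratio <- if (any(active)) mean(ratio[active]) else 0
  structure(list(wiring = wiring, activity = activity, ratio = ratio,
                 mean_ratio = mean_ratio, zero_wiring = zero),
            class = "energy_breakdown")
}

## Value-only objective: the node-averaged ratio over contributing nodes,
## without the per-node breakdown or zero-wiring warnings (hot path).
mean_objective <- function(W, V0, form = "post_post") {
  E <- rowSums(abs(W))
  A <- activity_cost(W, V0, form = form)
  active <- E > 0
  if (!any(active)) return(0)
  mean(A[active] / E[active])
}

#' @export
print.energy_breakdown <- function(x, ...) {
  n <- length(x$wiring)
  cat(sprintf("Energy breakdown over %d nodes\n", n))
  cat(sprintf("  mean wiring cost   E_w: %.6g\n", mean(x$wiring)))
  cat(sprintf("  mean activity cost E_a: %.6g\n", mean(x$activity)))
  cat(sprintf("  mean ratio  <E_a/E_w>: %.6g\n", x$mean_ratio))
  if (length(x$zero_wiring))
    cat(sprintf("  nodes with zero wiring: %d\n", length(x$zero_wiring)))
  invisible(x)
}
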