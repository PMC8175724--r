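## Boundedness constraints. Without them the normalized energy E_a/E_w can
## be driven down through two unphysical channels: diverging connection
## strength (E_w -> Inf) or a collapsing activity state (E_a -> 0). An
## upper weight bound blocks the first; a homeostatic rescaling toward an
## activity floor blocks the second.

#' Upper weight bound from the current weight statistics
#'
#' Computes the clipping bound \eqn{w_u = \langle|w|\rangle + n\sigma} where
#' the mean and the (population) standard deviation are taken over the
#' absolute values of all `N^2` entries of the current matrix. The bound is
#' recomputed from the evolving matrix at every epoch.
#'
#' @inheritParams propagate
#' @param n_sigma Number of standard deviations above the mean; must be
#'   positive (use `n_sigma = NULL` in [simulation_config()] for the
#'   unconstrained, no-limit condition).
#' @return Nonnegative scalar bound.
#' @export
compute_upper_bound <- function(W, n_sigma) {
  check_weights(W)
  if (!is.numeric(n_sigma) || length(n_sigma) != 1 || !is.finite(n_sigma) ||
      n_sigma <= 0)
    stop("`n_sigma` must be a positive finite scalar", call. = FALSE)
  a <- abs(W)
  m <- mean(a)
  s <- sqrt(mean((a - m)^2))  # population sd over all N^2 entries
  m + n_sigma * s
}

#' Clip connection strengths to an upper bound
#'
#' Entries with `|w| > w_u` are reduced to `sign(w) * w_u`; all others are
#' unchanged. Clipping preserves signs, never increases any `|w|`, and is
#' idempotent.
#'
#' @inheritParams propagate
#' @param w_u Nonnegative scalar bound.
#' @return The clipped weight matrix.
#' @export
clip_weights <- function(W, w_u) {
  check_weights(W)
  if (!is.numeric(w_u) || length(w_u) != 1 || !is.finite(w_u) || w_u < 0)
    stop("`w_u` must be a nonnegative finite scalar", call. = FALSE)
  over <- abs(W) > w_u
  if (any(over)) W[over] <- sign(W[over]) * w_u
  W
}

#' Homeostatic rescaling toward an activity floor
#'
#' When the node-averaged activity cost on a probe batch falls below the
#' floor \eqn{E_a^L = \alpha E_a^0}, every weight is multiplied by
#' \eqn{E_a^L / E_a}, mirroring homeostatic synaptic scaling. Because the
#' activity cost is homogeneous of degree 3 in the weights, an upward
#' rescale by `r > 1` multiplies the activity by `r^3 > r`, so the
#' constraint is strictly restored (and overshot, which is intentional: the
#' rule is applied exactly as stated).
#'
#' @inheritParams propagate
#' @param e_a_current Node-averaged activity cost measured on a probe
#'   batch; nonnegative.
#' @param e_a_floor Positive floor value.
#' @return The (possibly rescaled) weight matrix.
#' @export
enforce_activity_floor <- function(W, e_a_current, e_a_floor) {
  check_weights(W)
  if (!is.numeric(e_a_floor) || length(e_a_floor) != 1 || e_a_floor <= 0)
    stop("`e_a_floor` must be a positive scalar", call. = FALSE)
  if (!is.numeric(e_a_current) || length(e_a_current) != 1 || e_a_current < 0)
    stop("`e_a_current` must be a nonnegative scalar", call. = FALSE)
  if (e_a_current >= e_a_floor) return(W)
  if (e_a_current == 0)
    stop("activity collapse: E_a = 0 with a positive floor; rescaling cannot recover a zero state",
         call. = FALSE)
  W * (e_a_floor / e_a_current)
}
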