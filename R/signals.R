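## Random input-signal generation under the homogeneity assumption: the
## external drive is independent of the internal network state, so signals
## are drawn i.i.d. from a sparse spin distribution.

#' Generate a pool of random input signals
#'
#' Produces `n_signals` random activation vectors over `n_nodes` nodes. For
#' each vector a sparseness probability `p` is drawn uniformly in
#' `(0, p_max)`; each element is then nonzero with probability `p` and zero
#' otherwise. Under the default `sign_scheme = "split"` the nonzero
#' probability `p` is split evenly between +1 and -1; under
#' `"independent"` each sign occurs independently with probability `p`
#' (total nonzero probability `2p`, requiring `p_max <= 0.5`).
#'
#' @param n_signals Number of signal vectors to generate (one per row).
#' @param n_nodes Number of nodes `N` (vector dimension).
#' @param p_max Upper bound of the per-vector sparseness probability;
#'   default 0.5.
#' @param sign_scheme `"split"` (default) or `"independent"`; see Details.
#' @param seed Optional integer; when given, generation is reproducible and
#'   the caller's RNG state is left untouched.
#' @return Integer-valued `n_signals x n_nodes` matrix with entries in
#'   `{-1, 0, 1}`.
#' @examples
#' V0 <- generate_signals(100, 20, seed = 1)
#' mean(V0 != 0)  # about p_max / 2
#' @export
generate_signals <- function(n_signals, n_nodes, p_max = 0.5,
                             sign_scheme = c("split", "independent"),
                             seed = NULL) {
  sign_scheme <- match.arg(sign_scheme)
  if (!is.numeric(n_signals) || length(n_signals) != 1 || n_signals < 1)
    stop("`n_signals` must be a positive integer", call. = FALSE)
  if (!is.numeric(n_nodes) || length(n_nodes) != 1 || n_nodes < 1)
    stop("`n_nodes` must be a positive integer", call. = FALSE)
  if (!is.numeric(p_max) || p_max <= 0 || p_max > 1)
    stop("`p_max` must lie in (0, 1]", call. = FALSE)
  if (sign_scheme == "independent" && p_max > 0.5)
    stop("`p_max` must be <= 0.5 for the independent sign scheme",
         call. = FALSE)
  if (!is.null(seed)) {
    old <- rng_state()
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  B <- as.integer(n_signals)
  N <- as.integer(n_nodes)
  p <- stats::runif(B, 0, p_max)          # one sparseness level per vector
  u <- matrix(stats::runif(B * N), B, N)
  pn <- if (sign_scheme == "split") p else 2 * p
  nz <- u < pn                            # p recycles down columns: row b gets p[b]
  sgn <- matrix(sample(c(-1, 1), B * N, replace = TRUE), B, N)
  out <- matrix(0, B, N)
  out[nz] <- sgn[nz]
  out
}

rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng <- function(state) {
  if (is.null(state))
    suppressWarnings(rm(".Random.seed", envir = globalenv()))
  else
    assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
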