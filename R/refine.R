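## Training protocol: per epoch, normalize W by its mean absolute weight,
## run one pass of mini-batch Adam updates (each applied to W and,
## equivalently, to its transpose), restore the scale, then apply the two
## boundedness constraints (clip, then activity floor -- clipping can only
## lower the activity, so the floor check must come last).

#' Simulation configuration
#'
#' Collects every parameter of a refinement run. Defaults follow the
#' standard protocol: a 200-node network trained for 200 epochs of 10
#' batches over a pool of 10^4 random signals with Adam at learning rate
#' 0.01, starting from i.i.d. normal weights (mean 0, sd 0.5), with the
#' weight bound at `n_sigma = 5` standard deviations and the activity floor
#' at `alpha = 1e-3` times the initial activity cost.
#'
#' @param n_nodes Network size `N`.
#' @param n_epochs Number of training epochs.
#' @param batches_per_epoch Mini-batches per epoch; the pool is split into
#'   this many equal batches without replacement each epoch.
#' @param n_signals Size of the random-signal pool (must be divisible by
#'   `batches_per_epoch`).
#' @param learning_rate Adam step size.
#' @param init_mean,init_std Mean and standard deviation of the initial
#'   normal weights.
#' @param n_sigma Upper weight bound in units of the per-epoch standard
#'   deviation of `|w|`; `NULL` disables the bound (the no-limit case).
#' @param alpha Activity floor as a fraction of the initial activity cost;
#'   `NULL` or 0 disables the floor.
#' @param p_max Upper bound of the signal sparseness probability.
#' @param activity_form Activation state used on the partner side of the
#'   activity cost; see [activity_cost()].
#' @param sign_scheme Signal sign scheme; see [generate_signals()].
#' @param transpose_mode How the transpose refinement is applied per batch:
#'   `"sequential"` (default; a second Adam update on the transposed
#'   objective with its own optimizer state), `"averaged"` (symmetrized
#'   gradient, single state), or `"off"`.
#' @param seed Master seed; all randomness (initial weights, signal pool,
#'   batch shuffling) derives from it.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_nodes = 200, n_epochs = 200,
                              batches_per_epoch = 10, n_signals = 1e4,
                              learning_rate = 0.01, init_mean = 0,
                              init_std = 0.5, n_sigma = 5, alpha = 1e-3,
                              p_max = 0.5,
                              activity_form = c("post_post", "post_pre"),
                              sign_scheme = c("split", "independent"),
                              transpose_mode = c("sequential", "averaged", "off"),
                              seed = 1) {
  cfg <- list(
    n_nodes = as.integer(n_nodes), n_epochs = as.integer(n_epochs),
    batches_per_epoch = as.integer(batches_per_epoch),
    n_signals = as.integer(n_signals), learning_rate = learning_rate,
    init_mean = init_mean, init_std = init_std,
    n_sigma = if (is.null(n_sigma) || (length(n_sigma) == 1 && is.na(n_sigma))) NULL else n_sigma,
    alpha = if (is.null(alpha) || (length(alpha) == 1 && (is.na(alpha) || alpha == 0))) NULL else alpha,
    p_max = p_max,
    activity_form = match.arg(activity_form),
    sign_scheme = match.arg(sign_scheme),
    transpose_mode = match.arg(transpose_mode),
    seed = as.integer(seed))
  with(cfg, {
    if (n_nodes < 2 || n_epochs < 1 || batches_per_epoch < 1 || n_signals < 1)
      stop("all counts in the configuration must be positive", call. = FALSE)
    if (learning_rate < 0) stop("`learning_rate` must be nonnegative", call. = FALSE)
    if (init_std <= 0) stop("`init_std` must be positive", call. = FALSE)
    if (n_signals %% batches_per_epoch != 0)
      stop("`n_signals` must be divisible by `batches_per_epoch`", call. = FALSE)
    if (!is.null(n_sigma) && n_sigma <= 0)
      stop("`n_sigma` must be positive or NULL (no limit)", call. = FALSE)
    if (!is.null(alpha) && alpha <= 0)
      stop("`alpha` must be positive, or NULL/0 to disable the floor", call. = FALSE)
  })
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("Simulation config: N = %d, %d epochs x %d batches, pool %d signals\n",
              x$n_nodes, x$n_epochs, x$batches_per_epoch, x$n_signals))
  cat(sprintf("  weight bound: %s | activity floor alpha: %s\n",
              if (is.null(x$n_sigma)) "none" else sprintf("<|w|> + %g sd", x$n_sigma),
              if (is.null(x$alpha)) "none" else format(x$alpha)))
  cat(sprintf("  lr %g, init N(%g, %g), form %s, transpose %s, seed %d\n",
              x$learning_rate, x$init_mean, x$init_std, x$activity_form,
              x$transpose_mode, x$seed))
  invisible(x)
}

#' Initialize a random weight matrix
#'
#' Draws the `N x N` starting matrix with i.i.d. normal entries, signed
#' (excitatory and inhibitory) around `init_mean`.
#'
#' @param config A [simulation_config()].
#' @return An `N x N` numeric matrix.
#' @export
initialize_weights <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  N <- config$n_nodes
  matrix(stats::rnorm(N * N, config$init_mean, config$init_std), N, N)
}

## One training epoch. `state` carries the two Adam slots (forward and
## transpose), the floor value and the probe batch. Returns the updated
## matrix and per-epoch diagnostics.
epoch_step <- function(W, pool, config, state) {
  scale <- mean(abs(W))
  if (!is.finite(scale) || scale == 0)
    stop("degenerate weight scale before normalization", call. = FALSE)
  W <- W / scale

  B <- config$n_signals
  k <- config$batches_per_epoch
  bsize <- B %/% k
  idx <- sample.int(B)
  for (b in seq_len(k)) {
    batch <- pool[idx[((b - 1) * bsize + 1):(b * bsize)], , drop = FALSE]
    if (config$transpose_mode == "averaged") {
      g <- objective_gradient(W, batch, config$activity_form)$grad
      gt <- objective_gradient(t(W), batch, config$activity_form)$grad
      upd <- adam_step(state$adam_f, W, (g + t(gt)) / 2)
      W <- upd$W; state$adam_f <- upd$state
    } else {
      g <- objective_gradient(W, batch, config$activity_form)$grad
      upd <- adam_step(state$adam_f, W, g)
      W <- upd$W; state$adam_f <- upd$state
      if (config$transpose_mode == "sequential") {
        gt <- objective_gradient(t(W), batch, config$activity_form)$grad
        upd <- adam_step(state$adam_t, t(W), gt)
        W <- t(upd$W); state$adam_t <- upd$state
      }
    }
    if (!all(is.finite(W)))
      stop("non-finite weights during batch updates", call. = FALSE)
  }

  W <- W * scale

  w_u <- NA_real_
  if (!is.null(config$n_sigma)) {
    w_u <- compute_upper_bound(W, config$n_sigma)
    W <- clip_weights(W, w_u)
  }
  ea <- mean(activity_cost(W, state$probe, config$activity_form))
  rescale <- 1
  if (!is.null(state$floor) && ea < state$floor) {
    rescale <- state$floor / ea
    W <- enforce_activity_floor(W, ea, state$floor)
    ea <- mean(activity_cost(W, state$probe, config$activity_form))
  }
  obj <- mean_objective(W, state$probe, config$activity_form)
  if (!is.finite(obj))
    stop("non-finite objective at epoch end", call. = FALSE)
  ## A floor rescale multiplies every weight uniformly after clipping, so
  ## the bound the epoch-end matrix satisfies is w_u * rescale.
  list(W = W, state = state,
       diag = c(mean_ratio = obj, w_u = w_u, max_abs_w = max(abs(W)),
                e_a_probe = ea, floor_rescale = rescale))
}

#' Train a network by normalized-energy minimization
#'
#' Runs the full refinement protocol: initialize random weights, generate
#' the signal pool, and iterate [epoch_step] (mini-batch Adam on the
#' node-averaged `E_a/E_w` objective, transpose refinement, per-epoch
#' normalization, weight clipping and activity-floor rescaling) for
#' `n_epochs` epochs. Fully deterministic for a given `config$seed`.
#'
#' The per-epoch objective trace is evaluated on a fixed probe batch (the
#' first `n_signals / batches_per_epoch` signals of the pool) so values are
#' comparable across epochs. The floor reference `E_a^0` is measured on the
#' initial matrix against the same probe batch before any update.
#'
#' @param config A [simulation_config()].
#' @param verbose Print the objective every 10 epochs.
#' @return An object of class `trained_network`: list with `weights` and
#'   `initial_weights` (matrices), `trace` (data frame with one row per
#'   epoch: `epoch`, `mean_ratio`, `w_u`, `max_abs_w`, `e_a_probe`,
#'   `floor_rescale`), `e_a_initial`, `e_a_floor` and `config`.
#' @examples
#' cfg <- simulation_config(n_nodes = 20, n_epochs = 5, n_signals = 200,
#'                          seed = 7)
#' net <- refine_network(cfg)
#' tail(net$trace$mean_ratio, 1) < net$trace$mean_ratio[1]
#' @export
refine_network <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  old <- rng_state()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(config$seed)

  W0 <- initialize_weights(config)
  pool <- generate_signals(config$n_signals, config$n_nodes,
                           p_max = config$p_max,
                           sign_scheme = config$sign_scheme)
  probe <- pool[seq_len(config$n_signals %/% config$batches_per_epoch), ,
                drop = FALSE]
  e_a0 <- mean(activity_cost(W0, probe, config$activity_form))
  floor <- if (is.null(config$alpha)) NULL else config$alpha * e_a0

  state <- list(adam_f = adam_init(config$n_nodes, config$learning_rate),
                adam_t = adam_init(config$n_nodes, config$learning_rate),
                probe = probe, floor = floor)
  W <- W0
  trace <- matrix(NA_real_, config$n_epochs, 5,
                  dimnames = list(NULL, c("mean_ratio", "w_u", "max_abs_w",
                                          "e_a_probe", "floor_rescale")))
  for (ep in seq_len(config$n_epochs)) {
    step <- tryCatch(epoch_step(W, pool, config, state),
                     error = function(e)
                       stop(sprintf("epoch %d: %s", ep, conditionMessage(e)),
                            call. = FALSE))
    W <- step$W
    state <- step$state
    trace[ep, ] <- step$diag
    if (verbose && ep %% 10 == 0)
      message(sprintf("epoch %3d  mean ratio %.6g", ep, step$diag[["mean_ratio"]]))
  }
  trace_df <- data.frame(epoch = seq_len(config$n_epochs), trace)
  structure(list(weights = W, initial_weights = W0, trace = trace_df,
                 e_a_initial = e_a0, e_a_floor = floor, config = config),
            class = "trained_network")
}

#' @export
print.trained_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Trained network: N = %d, %d epochs (seed %d)\n",
              cfg$n_nodes, cfg$n_epochs, cfg$seed))
  cat(sprintf("  objective: %.6g (epoch 1) -> %.6g (final)\n",
              x$trace$mean_ratio[1], x$trace$mean_ratio[nrow(x$trace)]))
  cat(sprintf("  weight bound: %s | floor E_a^L: %s\n",
              if (is.null(cfg$n_sigma)) "none" else sprintf("%g sd", cfg$n_sigma),
              if (is.null(x$e_a_floor)) "none" else format(x$e_a_floor, digits = 4)))
  invisible(x)
}

#' Bin an objective trace into fixed-width epoch bins
#'
#' Averages the per-epoch objective over consecutive bins (default width
#' 10), the standard summary for convergence curves.
#'
#' @param trace The `trace` data frame of a [refine_network()] result.
#' @param bin_width Number of epochs per bin.
#' @return Data frame with columns `bin`, `epoch_mid` and `mean_ratio`.
#' @export
bin_trace <- function(trace, bin_width = 10) {
  stopifnot(is.data.frame(trace), bin_width >= 1)
  bins <- (trace$epoch - 1) %/% bin_width + 1
  agg <- tapply(trace$mean_ratio, bins, mean)
  mid <- tapply(trace$epoch, bins, mean)
  data.frame(bin = as.integer(names(agg)), epoch_mid = as.numeric(mid),
             mean_ratio = as.numeric(agg), row.names = NULL)
}
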