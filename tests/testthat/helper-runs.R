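# Shared trained networks for the comparison tests. Training is the
# expensive step, so runs are cached across test files; the reduced
# condition (N = 50, 50 epochs, full 1e4-signal pool) keeps one run in the
# seconds range while preserving the training protocol.

.run_cache <- new.env(parent = emptyenv())

reduced_config <- function(seed, limit = TRUE) {
  if (limit)
    simulation_config(n_nodes = 50, n_epochs = 50, n_sigma = 5,
                      alpha = 1e-3, seed = seed)
  else
    simulation_config(n_nodes = 50, n_epochs = 50, n_sigma = NULL,
                      alpha = NULL, seed = seed)
}

reduced_run <- function(seed, limit = TRUE) {
  key <- sprintf("%s-%d", if (limit) "lim" else "nol", seed)
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- refine_network(reduced_config(seed, limit))
  .run_cache[[key]]
}

# Full-protocol runs (N = 200, 200 epochs, 1e4 signals), bounded or not.
full_run <- function(seed = 1, limit = TRUE) {
  key <- sprintf("full-%s-%d", if (limit) "lim" else "nol", seed)
  if (is.null(.run_cache[[key]])) {
    cfg <- if (limit) simulation_config(seed = seed)
           else simulation_config(n_sigma = NULL, alpha = NULL, seed = seed)
    .run_cache[[key]] <- refine_network(cfg)
  }
  .run_cache[[key]]
}
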