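test_that("initial weights follow the configured normal distribution", {
  cfg <- simulation_config(n_nodes = 200, seed = 42)
  set.seed(cfg$seed)
  W <- initialize_weights(cfg)
  n <- length(W)
  expect_lt(abs(mean(W)), 3 * 0.5 / sqrt(n))
  expect_lt(abs(sd(W) - 0.5), 3 * 0.5 / sqrt(2 * (n - 1)))
})

test_that("training is exactly reproducible from the master seed", {
  cfg <- simulation_config(n_nodes = 15, n_epochs = 3, n_signals = 200,
                           batches_per_epoch = 4, seed = 31)
  a <- refine_network(cfg)
  b <- refine_network(cfg)
  expect_identical(a$weights, b$weights)
  expect_identical(a$trace, b$trace)
  expect_false(identical(
    a$weights,
    refine_network(simulation_config(n_nodes = 15, n_epochs = 3,
                                     n_signals = 200, batches_per_epoch = 4,
                                     seed = 32))$weights))
})

test_that("the trace has one row per epoch and bins average correctly", {
  net <- reduced_run(1)
  expect_equal(nrow(net$trace), 50)
  b <- bin_trace(net$trace)
  expect_equal(nrow(b), 5)
  expect_equal(b$mean_ratio[2], mean(net$trace$mean_ratio[11:20]))
})

test_that("the objective decreases over training at reduced scale", {
  net <- reduced_run(1)
  expect_lt(net$trace$mean_ratio[50], net$trace$mean_ratio[1])
  # windowed means are non-increasing
  b <- bin_trace(net$trace)$mean_ratio
  expect_true(all(diff(b) <= 0))
})

test_that("without limits the objective decreases without stabilizing", {
  net <- reduced_run(1, limit = FALSE)
  b <- bin_trace(net$trace)$mean_ratio
  expect_true(all(diff(b) < 0))
  expect_true(all(b[length(b)] < b[-length(b)]))
})

test_that("weight limits make independently seeded runs more similar", {
  lim <- lapply(1:5, function(s) reduced_run(s)$weights)
  nol <- lapply(1:5, function(s) reduced_run(s, limit = FALSE)$weights)
  expect_lt(stability_rmse(lim), stability_rmse(nol))
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(simulation_config(n_signals = 105, batches_per_epoch = 10),
               "divisible")
  expect_error(simulation_config(n_sigma = -1), "positive")
  expect_error(simulation_config(learning_rate = -0.1), "nonnegative")
  expect_error(simulation_config(init_std = 0), "positive")
  cfg <- simulation_config(n_sigma = NULL, alpha = 0)
  expect_null(cfg$n_sigma)
  expect_null(cfg$alpha)
})
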