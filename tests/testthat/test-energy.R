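test_that("propagate applies the linear state transition", {
  expect_equal(propagate(diag(3), matrix(c(1, -1, 0), 1)),
               matrix(c(1, -1, 0), 1))
  expect_equal(propagate(matrix(0, 3, 3), rand_signals(4, 3)),
               matrix(0, 4, 3))
  W <- matrix(c(0, 2, -1, 0), 2, 2, byrow = TRUE)
  expect_equal(propagate(W, matrix(c(1, 1), 1)), matrix(c(2, -1), 1))
  expect_error(propagate(diag(3), matrix(1, 1, 4)), "3.*4|4.*3")
})

test_that("wiring cost is the row sum of absolute weights", {
  expect_equal(wiring_cost(diag(4)), rep(1, 4))
  expect_equal(wiring_cost(matrix(c(0, -3, 2, 0), 2, 2, byrow = TRUE)),
               c(3, 2))
})

test_that("activity cost matches hand evaluation and zero cases", {
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  V0 <- matrix(c(1, 1), 1)
  expect_equal(activity_cost(W, V0), c(1, 1))
  expect_equal(activity_cost(W, matrix(0, 3, 2)), c(0, 0))
  expect_equal(activity_cost(matrix(0, 2, 2), V0), c(0, 0))
})

test_that("vectorized activity cost equals the triple-loop oracle", {
  set.seed(11)
  for (form in c("post_post", "post_pre")) {
    for (rep in 1:5) {
      N <- sample(2:5, 1)
      B <- sample(1:3, 1)
      W <- rand_weights(N)
      V0 <- rand_signals(B, N)
      expect_equal(activity_cost(W, V0, form = form),
                   activity_cost_naive(W, V0, form = form),
                   tolerance = 1e-12)
    }
  }
})

test_that("normalized energy combines costs and handles zero-wiring rows", {
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  e <- normalized_energy(W, matrix(c(1, 1), 1))
  expect_equal(e$ratio, c(1, 1))
  expect_equal(e$mean_ratio, 1)

  Wz <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE)  # node 1 disconnected
  expect_warning(ez <- normalized_energy(Wz, matrix(c(1, 1), 1)),
                 "zero wiring")
  expect_equal(ez$zero_wiring, 1L)
  expect_true(is.na(ez$ratio[1]))
  expect_equal(ez$mean_ratio, ez$ratio[2])
})

test_that("energy terms are nonnegative for arbitrary inputs", {
  set.seed(7)
  for (rep in 1:100) {
    N <- sample(2:8, 1)
    W <- rand_weights(N)
    V0 <- rand_signals(sample(1:5, 1), N)
    expect_true(all(wiring_cost(W) >= 0))
    expect_true(all(activity_cost(W, V0) >= 0))
  }
})

test_that("costs obey their homogeneity laws in the weights", {
  set.seed(21)
  W <- rand_weights(6)
  V0 <- rand_signals(4, 6)
  base_w <- wiring_cost(W)
  base_a <- activity_cost(W, V0)
  base_r <- normalized_energy(W, V0)$mean_ratio
  for (c in c(0.5, 2, 10)) {
    expect_equal(wiring_cost(c * W), c * base_w, tolerance = 1e-10)
    expect_equal(activity_cost(c * W, V0), c^3 * base_a, tolerance = 1e-10)
    expect_equal(normalized_energy(c * W, V0)$mean_ratio, c^2 * base_r,
                 tolerance = 1e-10)
  }
})

test_that("wiring cost ignores signals; sign flips keep costs nonnegative", {
  set.seed(31)
  W <- rand_weights(5)
  V0 <- rand_signals(3, 5)
  V0f <- V0
  nz <- which(V0f != 0)[1]
  V0f[nz] <- -V0f[nz]
  expect_identical(wiring_cost(W), wiring_cost(W))
  expect_true(all(activity_cost(W, V0f) >= 0))
})
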