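test_that("node strength matches the wiring-cost definition", {
  expect_equal(node_strength(diag(5)), rep(1, 5))
  expect_equal(node_strength(matrix(c(0, -3, 2, 0), 2, 2, byrow = TRUE)),
               c(3, 2))
})

test_that("strength quantile sampling matches a direct rank lookup", {
  # length-101 staircase: the n-th point must sit exactly at rank n+1
  v <- 101:1
  d <- strength_distribution(v, 100)
  expect_equal(nrow(d), 100)
  expect_equal(d$probability, (1:100) / 101)
  ranks <- pmin(pmax(round(d$probability * 101), 1), 101)
  expect_equal(d$strength, sort(v, decreasing = TRUE)[ranks] / max(v))

  # constant vector -> flat line at 1
  expect_true(all(strength_distribution(rep(3, 40))$strength == 1))

  # fewer values than points -> all values used, probabilities rescaled
  d65 <- strength_distribution(runif(65), 100)
  expect_equal(nrow(d65), 65)
  expect_equal(d65$probability, (1:65) / 66)
  expect_true(all(diff(d65$strength) <= 0))

  expect_error(strength_distribution(rep(0, 10)), "degenerate")
})

test_that("pooled multi-run strengths yield one distribution", {
  set.seed(2)
  pooled <- unlist(lapply(1:4, function(i) runif(30, 0.1, 1)))
  d <- strength_distribution(pooled, 100)
  expect_equal(nrow(d), 100)
  expect_true(all(diff(d$strength) <= 0))
  expect_true(all(d$strength > 0 & d$strength <= 1))
})

test_that("stability RMSE is zero for identical or permuted networks", {
  set.seed(3)
  W <- rand_weights(6)
  expect_equal(stability_rmse(list(W, W)), 0)
  P <- matrix(sample(as.vector(W)), 6, 6)
  expect_equal(stability_rmse(list(W, P)), 0)
  expect_equal(stability_rmse(list(W, 3 * P)), 0)  # mean-normalization
})

test_that("stability RMSE reproduces a hand-computed pair value", {
  # ordered normalized magnitudes (2, 1, 0.5, 0.5) vs (1.5, 1.5, 0.5, 0.5)
  W1 <- matrix(c(2, -1, 0.5, 0.5), 2, 2)
  W2 <- matrix(c(-1.5, 1.5, 0.5, 0.5), 2, 2)
  expect_equal(stability_rmse(list(W1, W2)), sqrt(0.125), tolerance = 1e-12)
})

test_that("stability RMSE reports shape mismatches by pair", {
  expect_error(stability_rmse(list(diag(3), diag(4))), "1.*3x3.*2.*4x4")
  expect_error(stability_rmse(list(diag(3))), "at least two")
})

test_that("max cluster size agrees with the brute-force degree oracle", {
  expect_equal(max_cluster_size(star_matrix(12), 1), 11)
  # perfect matching: all degrees 1
  M <- matrix(0, 6, 6)
  M[cbind(c(1, 3, 5), c(2, 4, 6))] <- 1
  M <- M + t(M)
  expect_lte(max_cluster_size(M, 0.5), 1)
  expect_equal(max_cluster_size(M, 1), 1)
  set.seed(5)
  for (rep in 1:20) {
    W <- rand_weights(8)
    W[sample(64, 30)] <- 0
    expect_equal(max_cluster_size(W, 1), max_degree_oracle(W))
  }
  # fewer than one connection selected
  expect_equal(max_cluster_size(star_matrix(5), 0.01), 0L)
})

test_that("cluster curves are monotone, normalized, and match pointwise", {
  set.seed(6)
  for (rep in 1:300) {
    N <- sample(4:8, 1)
    W <- rand_weights(N)
    W[sample(N * N, floor(N * N / 2))] <- 0
    cc <- cluster_curve(W)
    expect_true(all(diff(cc$size) >= 0))
    expect_true(all(cc$size >= 0 & cc$size <= 1))
    if (sum(W != 0 & !diag(TRUE, N)) > 0)
      expect_equal(cc$size[nrow(cc)], 1)
  }
  # the incremental curve equals independent per-ratio evaluation
  set.seed(61)
  W <- rand_weights(15)
  W[sample(225, 100)] <- 0
  cc <- cluster_curve(W)
  full <- max_cluster_size(W, 1)
  for (r in c(0.05, 0.2, 0.5, 0.77, 1))
    expect_equal(cc$size[which.min(abs(cc$ratio - r))],
                 max_cluster_size(W, r) / full)
})

test_that("star cluster curve grows linearly to the hub degree", {
  W <- star_matrix(20, weights = seq(19, 1))  # distinct weights, no ties
  cc <- cluster_curve(W)
  expect_equal(cc$size[nrow(cc)], 1)
  # with 2*19 arcs forming 19 undirected pairs, size(r) ~ selected pairs/19
  mid <- cc[cc$ratio %in% c(0.25, 0.5, 0.75), ]
  expect_equal(mid$size, ceiling(floor(mid$ratio * 38) / 2) / 19)
})

test_that("degree-product weighting matches hand cases", {
  A <- (star_matrix(8) != 0) * 1
  W <- degree_product_weights(A)
  expect_equal(unique(W[W != 0]), 7)
  K <- matrix(1, 5, 5) - diag(5)
  expect_true(all(degree_product_weights(K)[K == 1] == 16))
  expect_equal(degree_product_weights(matrix(0, 4, 4)), matrix(0, 4, 4))
  expect_error(degree_product_weights(matrix(0.5, 3, 3)), "binary")
})

test_that("synthetic hubby networks have more dispersed strengths than random", {
  rec_flat <- synth_connectome(100, hubness = 0, density = 0.5, seed = 9)
  rec_hub <- synth_connectome(100, hubness = 2, density = 0.5, seed = 9)
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(node_strength(rec_flat$matrix)),
            cv(node_strength(rec_hub$matrix)))
})
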