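# Small fixtures and independent oracles, built in code.

# Star graph weight matrix: node 1 connected to all others (symmetric),
# optionally with distinct weights so strength ordering is unambiguous.
star_matrix <- function(n, weights = NULL) {
  W <- matrix(0, n, n)
  w <- if (is.null(weights)) rep(1, n - 1) else weights
  W[1, 2:n] <- w
  W[2:n, 1] <- w
  W
}

rand_weights <- function(n, sd = 1) matrix(rnorm(n * n, 0, sd), n, n)

rand_signals <- function(b, n) matrix(sample(c(-1, 0, 1), b * n, replace = TRUE), b, n)

# Naive triple-loop evaluation of the activity cost: the independent oracle
# for the vectorized implementation.
activity_cost_naive <- function(W, V0, form = "post_post") {
  N <- nrow(W); B <- nrow(V0)
  V <- matrix(0, B, N)
  for (b in 1:B) for (i in 1:N) V[b, i] <- sum(W[i, ] * V0[b, ])
  X <- if (form == "post_post") V else V0
  ea <- numeric(N)
  for (i in 1:N) {
    acc <- 0
    for (b in 1:B) for (j in 1:N) acc <- acc + abs(V[b, i] * W[i, j] * X[b, j])
    ea[i] <- acc / B
  }
  ea
}

# Central finite-difference gradient of the mean-ratio objective.
numeric_gradient <- function(W, V0, form = "post_post", h = 1e-6) {
  f <- function(M) {
    E <- rowSums(abs(M))
    A <- activity_cost(M, V0, form = form)
    mean(A[E > 0] / E[E > 0])
  }
  g <- matrix(0, nrow(W), ncol(W))
  for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W))) {
    Wp <- W; Wm <- W
    Wp[i, j] <- W[i, j] + h
    Wm[i, j] <- W[i, j] - h
    g[i, j] <- (f(Wp) - f(Wm)) / (2 * h)
  }
  g
}

# Brute-force maximum undirected degree of the nonzero support (diagonal
# excluded): oracle for max_cluster_size at r = 1.
max_degree_oracle <- function(W) {
  A <- (W != 0) | (t(W) != 0)
  diag(A) <- FALSE
  max(rowSums(A))
}
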