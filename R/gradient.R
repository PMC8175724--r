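## Analytic gradient of the training objective
##
##   f(W) = (1/N') sum_{i : E_w(i) > 0}  E_a(i) / E_w(i)
##
## with E_w(i) = sum_j |w_ij| and, for the default post_post form,
## E_a(i) = (1/B) sum_b sum_j |v_bi w_ij v_bj|,  v_b = W v0_b.
##
## Writing s = sign of each product term and using d|x|/dx = sign(x) with
## subgradient 0 at x = 0, the derivative of E_a(i) w.r.t. w_kl splits into
## a direct term (the w_kl inside the |.|) and two chain terms through
## v_bk = sum_l w_kl v0_bl. All three reduce to dense matrix products
## because |v_bi w_ij x_bj| = |v_bi| |w_ij| |x_bj|:
##
##   direct:   c_k (1/B) sum_b |v_bk||v_bl| sign(w_kl)
##   chain i:  c_k (1/B) sum_b sign(v_bk) (|W| |v_b|)_k v0_bl
##   chain j:  (1/B) sum_b sign(v_bk) (c |v_b|)^T |W|_{.,k} v0_bl
##
## with c_i = 1/(N' E_w(i)) for contributing nodes and 0 otherwise. The
## wiring part contributes -(1/N') (E_a(k)/E_w(k)^2) sign(w_kl). For the
## post_pre form the partner activation is v0 (independent of W), so the
## second chain term vanishes and |v| is replaced by |v0| on the j side.

#' Objective value and analytic gradient
#'
#' Evaluates the node-averaged normalized energy (the quantity minimized by
#' [refine_network()]) together with its exact gradient with respect to
#' every weight. The gradient uses subgradient 0 wherever an absolute value
#' sits at 0, so exactly-zero weights are stationary for the direct term.
#'
#' @inheritParams activity_cost
#' @return List with `value` (scalar mean ratio over nodes with positive
#'   wiring cost) and `grad` (an `N x N` matrix).
#' @seealso [normalized_energy()] for the value alone with a per-node
#'   breakdown.
#' @export
objective_gradient <- function(W, V0, form = c("post_post", "post_pre")) {
  form <- match.arg(form)
  check_weights(W)
  check_signals(V0)
  check_dims(W, V0)
  N <- nrow(W)
  B <- nrow(V0)
  absW <- abs(W)
  sgnW <- sign(W)
  V <- V0 %*% t(W)
  absV <- abs(V)
  sgnV <- sign(V)

  E <- rowSums(absW)
  if (form == "post_post") {
    R <- absV %*% t(absW)                 # R[b,i] = sum_j |w_ij||v_bj|
    A <- colMeans(absV * R)
  } else {
    absV0 <- abs(V0)
    R <- absV0 %*% t(absW)
    A <- colMeans(absV * R)
  }

  active <- E > 0
  n_act <- sum(active)
  if (n_act == 0)
    return(list(value = 0, grad = matrix(0, N, N)))
  cvec <- ifelse(active, 1 / (n_act * E), 0)
  value <- sum(A[active] / E[active]) / n_act

  if (form == "post_post") {
    G1 <- (cvec * crossprod(absV)) / B * sgnW
    P <- sgnV * R                         # P[b,k] = sign(v_bk) (|W||v_b|)_k
    G2 <- (cvec * crossprod(P, V0)) / B
    absVc <- absV * rep(cvec, each = B)   # column i scaled by c_i
    Q <- sgnV * (absVc %*% absW)          # Q[b,k] = sign(v_bk) sum_i c_i|v_bi||w_ik|
    G3 <- crossprod(Q, V0) / B
    GA <- G1 + G2 + G3
  } else {
    G1 <- (cvec * crossprod(absV, absV0)) / B * sgnW
    P <- sgnV * R
    G2 <- (cvec * crossprod(P, V0)) / B
    GA <- G1 + G2
  }

  dvec <- ifelse(active, A / (n_act * E^2), 0)
  grad <- GA - dvec * sgnW
  list(value = value, grad = grad)
}

## Minimal Adam optimizer state: first/second moment matrices and step
## counter, canonical hyperparameters unless overridden.
adam_init <- function(N, learning_rate = 0.01, beta1 = 0.9, beta2 = 0.999,
                      epsilon = 1e-8) {
  list(m = matrix(0, N, N), v = matrix(0, N, N), t = 0L,
       lr = learning_rate, beta1 = beta1, beta2 = beta2, eps = epsilon)
}

adam_step <- function(state, W, grad) {
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * grad
  state$v <- state$beta2 * state$v + (1 - state$beta2) * grad^2
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  W <- W - state$lr * mhat / (sqrt(vhat) + state$eps)
  list(W = W, state = state)
}
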