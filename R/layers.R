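# Lipschitz-constrained linear layers.
#
# Every layer stores a raw weight matrix, a bias, and a learnable scalar c*.
# The effective weights used in the forward pass are
#     W_eff = W_raw / sigma_max(W_raw) * softplus(c*),
# so softplus(c*) is the layer's spectral norm (and Lipschitz constant, up to
# the activation).  sigma_max is approximated by power iteration with
# persistent, warm-started left/right vectors.

new_lipschitz_layer <- function(n_out, n_in) {
  bound <- 1 / sqrt(n_in)
  W <- matrix(stats::runif(n_out * n_in, -bound, bound), n_out, n_in)
  b <- stats::runif(n_out, -bound, bound)
  u <- stats::rnorm(n_out); u <- u / sqrt(sum(u^2))
  v <- stats::rnorm(n_in);  v <- v / sqrt(sum(v^2))
  layer <- list(W = W, b = b, u = u, v = v)
  # c* chosen so softplus(c*) equals the initial spectral norm: the scaled
  # weights start out identical to the raw initialization.  The converged
  # singular vectors are kept as the warm start.
  pi_ <- power_iteration(layer, n_iter = 50L)
  layer$u <- pi_$u; layer$v <- pi_$v
  layer$c_star <- softplus_inv(pi_$sigma)
  layer
}

power_iteration <- function(layer, n_iter = 2L) {
  W <- layer$W; u <- layer$u; v <- layer$v
  for (i in seq_len(n_iter)) {
    v <- drop(crossprod(W, u)); v <- v / max(sqrt(sum(v^2)), 1e-12)
    u <- drop(W %*% v);         u <- u / max(sqrt(sum(u^2)), 1e-12)
  }
  sigma <- max(drop(crossprod(u, W %*% v)), 1e-12)
  list(sigma = sigma, u = u, v = v)
}

#' Spectral norm estimate by power iteration
#'
#' Rayleigh-quotient estimate of the largest singular value of a weight
#' matrix, with optional warm-start state (persistent left/right vectors).
#' The estimate never exceeds the true spectral norm and converges to it as
#' `n_iter` grows.
#'
#' @param weights numeric matrix
#' @param n_iter number of power iterations (the training loop uses 2 with
#'   warm-started vectors)
#' @param state optional list with unit vectors `u`, `v` from a previous call
#' @return list with `sigma` (the estimate) and updated `u`, `v`
#' @examples
#' spectral_norm_estimate(diag(c(3, 1)), n_iter = 10)$sigma
#' @export
spectral_norm_estimate <- function(weights, n_iter = 2L, state = NULL) {
  if (all(weights == 0)) {
    return(list(sigma = 1e-12,
                u = c(1, rep(0, nrow(weights) - 1L)),
                v = c(1, rep(0, ncol(weights) - 1L))))
  }
  if (is.null(state)) {
    u <- rep(1, nrow(weights)); u <- u / sqrt(sum(u^2))
    v <- rep(1, ncol(weights)); v <- v / sqrt(sum(v^2))
    state <- list(u = u, v = v)
  }
  power_iteration(list(W = weights, u = state$u, v = state$v), n_iter = n_iter)
}

# Effective (spectrally normalized and rescaled) weights of a layer, plain
# numeric path.  n_iter = 50 is used when freezing a model for prediction so
# sigma is converged; the training path uses the tape version below.
layer_effective <- function(layer, n_iter = 50L) {
  pi_ <- power_iteration(layer, n_iter = n_iter)
  layer$W / pi_$sigma * softplus(layer$c_star)
}

# Tape version: W, b, c_star are tape nodes; u, v are detached numerics that
# the caller refreshes (2 warm-started iterations per optimizer step).
layer_effective_tape <- function(tape, Wnode, cnode, u, v) {
  Wv <- t_mm(tape, Wnode, matrix(v, ncol = 1L))
  sigma <- t_sum(tape, t_emul(tape, Wv, matrix(u, ncol = 1L)))
  scale <- t_ediv(tape, t_softplus(tape, cnode), sigma)
  t_emul(tape, Wnode, scale)
}
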