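# Plain-numeric forward pass with analytic jet propagation.
#
# Activity coefficients are composition derivatives of gE/(RT); the excess
# enthalpy is a temperature derivative; the stability criterion needs a
# second composition derivative.  Instead of finite differences, first- and
# second-order Taylor jets (value, d/dX, d2/dX2, d/dT*) are propagated
# analytically through the networks, so every derivative is exact for the
# implemented forward pass.  The tape in tape.R mirrors the same propagation
# for training.

# One linear layer applied to a jet. J is list(v, dX, dT, d2X); NULL means an
# identically-zero jet component.
jet_linear <- function(W, b, J) {
  list(v   = W %*% J$v + b,
       dX  = if (is.null(J$dX))  NULL else W %*% J$dX,
       dT  = if (is.null(J$dT))  NULL else W %*% J$dT,
       d2X = if (is.null(J$d2X)) NULL else W %*% J$d2X)
}

jet_silu <- function(J) {
  f1 <- silu_d(J$v, 1L)
  d2 <- NULL
  if (!is.null(J$dX)) {
    f2 <- silu_d(J$v, 2L)
    d2 <- f2 * J$dX * J$dX
    if (!is.null(J$d2X)) d2 <- d2 + f1 * J$d2X
  }
  list(v = silu_d(J$v, 0L),
       dX = if (is.null(J$dX)) NULL else f1 * J$dX,
       dT = if (is.null(J$dT)) NULL else f1 * J$dT,
       d2X = d2)
}

jet_add <- function(A, B) {
  sum0 <- function(a, b) if (is.null(a)) b else if (is.null(b)) a else a + b
  list(v = A$v + B$v, dX = sum0(A$dX, B$dX), dT = sum0(A$dT, B$dT),
       d2X = sum0(A$d2X, B$d2X))
}

# Refined embeddings for scaled embeddings Estar (D x n).
network_theta <- function(model, Estar, Weff = network_weff(model)) {
  silu_d(Weff$emb %*% Estar + model$layers$emb$b, 0L)
}

#' Refine embeddings and compute pairwise similarity
#'
#' Applies the embedding network to the scaled embeddings and evaluates the
#' RBF similarity `R_ij = exp(-beta ||theta_i - theta_j||^2)` on its raw
#' output.  The diagonal is exactly 1, as is any pair with bitwise-identical
#' embeddings.
#'
#' @param model a `gibbsnn_network`
#' @param components components data frame (or D x N embedding matrix)
#' @return list with `theta` (width x N) and `R` (N x N)
#' @export
refine_and_similarity <- function(model, components) {
  E <- if (is.matrix(components)) components else embedding_matrix(components)
  if (nrow(E) != model$D)
    stop(sprintf("embedding dimension %d does not match network input %d",
                 nrow(E), model$D))
  theta <- network_theta(model, scale_embeddings(model$scalers, E))
  list(theta = theta, R = similarity_matrix(theta, model$beta_rbf))
}

similarity_matrix <- function(theta, beta) {
  n <- ncol(theta)
  G <- crossprod(theta)
  nn <- diag(G)
  d2 <- pmax(outer(nn, nn, "+") - 2 * G, 0)
  R <- exp(-beta * d2)
  R[d2 == 0] <- 1
  diag(R) <- 1
  R
}

#' Lump mole fractions by component similarity
#'
#' `x_tilde_i = sum_j x_j R_ij`: identical components (similarity 1) are
#' merged into one effective component before the binary projection.
#'
#' @param x mole fractions (length N, summing to 1)
#' @param R N x N similarity matrix
#' @return corrected mole fractions, length N
#' @export
lump_mole_fractions <- function(x, R) as.numeric(R %*% x)

#' Project lumped fractions onto a binary subsystem
#'
#' Symmetric projection `X_i = (1 + x_i - x_j)/2`; `X_i + X_j = 1` exactly,
#' and for a binary mixture the projection returns the lumped fractions
#' unchanged.  It has no singular points at infinite dilution.
#'
#' @param x_tilde lumped mole fractions
#' @param i,j component indices (i != j)
#' @return c(Xi, Xj)
#' @export
muggianu_project <- function(x_tilde, i, j) {
  stopifnot(i != j)
  # half-difference form: exactly antisymmetric under i <-> j, so swapping
  # the subsystem order swaps (Xi, Xj) bitwise
  d <- (x_tilde[i] - x_tilde[j]) / 2
  c(0.5 + d, 0.5 - d)
}

# Batched deep-set interaction for pairs.  theta_i, theta_j: width x P;
# X: projected fraction of branch i (length P); Tstar scalar or length P.
# Returns rows phi, phiX, phiXX, phiT (each length P) where the X-derivative
# direction is (+1 on branch i's fraction slot, -1 on branch j's).
pair_interaction_jets <- function(model, Weff, theta_i, theta_j, X, Tstar,
                                  need_d2 = FALSE, need_dT = TRUE,
                                  Xj = NULL) {
  P <- length(X)
  w <- model$width
  if (is.null(Xj)) Xj <- 1 - X
  Tr <- rep(Tstar, length.out = P)
  V <- cbind(rbind(theta_i, X, Tr), rbind(theta_j, Xj, Tr))
  dX <- matrix(0, w + 2L, 2L * P)
  dX[w + 1L, ] <- c(rep(1, P), rep(-1, P))
  dT <- NULL
  if (need_dT) { dT <- matrix(0, w + 2L, 2L * P); dT[w + 2L, ] <- 1 }
  J <- list(v = V, dX = dX, dT = dT, d2X = NULL)
  J <- jet_silu(jet_linear(Weff$mix1, model$layers$mix1$b, J))
  J <- jet_silu(jet_linear(Weff$mix2, model$layers$mix2$b, J))
  Ai <- lapply(J, function(m) if (is.null(m)) NULL else m[, seq_len(P), drop = FALSE])
  Aj <- lapply(J, function(m) if (is.null(m)) NULL else m[, P + seq_len(P), drop = FALSE])
  J <- jet_add(Ai, Aj)
  if (!need_d2) J$d2X <- NULL
  J <- jet_silu(jet_linear(Weff$prop1, model$layers$prop1$b, J))
  J <- jet_linear(Weff$prop2, model$layers$prop2$b, J)
  list(phi = drop(J$v), phiX = drop(J$dX),
       phiXX = if (is.null(J$d2X)) NULL else drop(J$d2X),
       phiT = if (is.null(J$dT)) NULL else drop(J$dT))
}

# Full N-component evaluation at one state point.
# Returns gE/RT, its gradient w.r.t. x_1..x_{N-1} (x_N eliminated), ln gamma,
# hE [J/mol] and per-subsystem diagnostics.
gibbsnn_eval <- function(model, E, x, T, need_hE = TRUE) {
  N <- length(x)
  stopifnot(N >= 2L, ncol(E) == N)
  if (T <= 0) stop("temperature must be positive (K)")
  x <- close_simplex(x)
  check_mole_fractions(x)
  sc <- model$scalers
  Tstar <- scale_temperature(sc, T)
  Weff <- network_weff(model)
  theta <- network_theta(model, scale_embeddings(sc, E), Weff)
  R <- similarity_matrix(theta, model$beta_rbf)
  xt <- as.numeric(R %*% x)

  pr <- utils::combn(N, 2L)
  P <- ncol(pr)
  ii <- pr[1L, ]; jj <- pr[2L, ]
  dd <- (xt[ii] - xt[jj]) / 2
  Xi <- 0.5 + dd
  s <- 1 - R[cbind(ii, jj)]

  if (!is.null(model$q_fun)) {
    qf <- model$q_fun(Xi, T)
    q <- qf$q; qd1 <- qf$qX; qTs <- qf$qT * sc$t_std
  } else {
    jets <- pair_interaction_jets(model, Weff, theta[, ii, drop = FALSE],
                                  theta[, jj, drop = FALSE], Xi, Tstar,
                                  Xj = 0.5 - dd)
    q <- s * jets$phi
    qd1 <- s * jets$phiX           # dq/dX_i^(ij)
    qTs <- s * jets$phiT           # dq/dT*
  }

  pre <- x[ii] * x[jj]
  g <- sum(pre * q)

  # dX_i^(ij)/dx_k for k = 1..N-1 with x_N = 1 - sum(x_1..x_{N-1}).
  dgdx <- numeric(N - 1L)
  for (k in seq_len(N - 1L)) {
    dpre <- (ii == k) * x[jj] + ((jj == k) - (jj == N)) * x[ii]
    u <- (R[cbind(ii, k)] - R[cbind(ii, N)] - R[cbind(jj, k)] + R[cbind(jj, N)]) / 2
    dgdx[k] <- sum(dpre * q + pre * qd1 * u)
  }
  corr <- sum(x[seq_len(N - 1L)] * dgdx)
  lng <- c(g + dgdx - corr, g - corr)

  hE <- if (need_hE) -GAS_R * T^2 / sc$t_std * sum(pre * qTs) else NULL
  list(gE_RT = g, dgdx = dgdx, ln_gamma = lng, hE = hE,
       subsystems = data.frame(i = ii, j = jj, Xi = Xi, Xj = 1 - Xi,
                               R_ij = R[cbind(ii, jj)], q_ij = q,
                               gE_ij_RT = pre * q))
}

# Vectorized binary evaluation over a composition grid at fixed T.
# Returns g (= gE/RT), first/second x1-derivatives, ln gamma and hE.
gibbsnn_binary_eval <- function(model, E, x1, T, need_d2 = FALSE,
                                need_hE = FALSE) {
  stopifnot(ncol(E) == 2L)
  sc <- model$scalers
  Tstar <- scale_temperature(sc, T)
  Weff <- network_weff(model)
  theta <- network_theta(model, scale_embeddings(sc, E), Weff)
  r <- similarity_matrix(theta, model$beta_rbf)[1L, 2L]
  s <- 1 - r
  dd <- s * (x1 - 0.5)
  X1 <- 0.5 + dd

  if (!is.null(model$q_fun)) {
    qf <- model$q_fun(X1, T)
    q <- qf$q; qd1 <- qf$qX; qd2 <- qf$qXX; qTs <- qf$qT * sc$t_std
  } else {
    P <- length(x1)
    jets <- pair_interaction_jets(model, Weff,
                                  theta[, rep(1L, P), drop = FALSE],
                                  theta[, rep(2L, P), drop = FALSE],
                                  X1, Tstar, need_d2 = need_d2,
                                  need_dT = need_hE, Xj = 0.5 - dd)
    q <- s * jets$phi
    qd1 <- s * jets$phiX
    qd2 <- if (need_d2) s * jets$phiXX else NULL
    qTs <- if (need_hE) s * jets$phiT else NULL
  }

  x2 <- 1 - x1
  g  <- x1 * x2 * q
  dg <- (1 - 2 * x1) * q + x1 * x2 * s * qd1
  d2g <- if (!is.null(qd2)) -2 * q + 2 * (1 - 2 * x1) * s * qd1 +
           x1 * x2 * s^2 * qd2 else NULL
  list(g = g, dg = dg, d2g = d2g,
       ln_gamma1 = g + x2 * dg, ln_gamma2 = g - x1 * dg,
       hE = if (!is.null(qTs)) -GAS_R * T^2 / sc$t_std * x1 * x2 * qTs else NULL)
}

#' Excess Gibbs energy of a mixture
#'
#' @param model a `gibbsnn_network`
#' @param components components data frame (rows in the order of `x`) or
#'   D x N embedding matrix
#' @param x mole fractions (length N; the last one is reconstructed from the
#'   summation condition)
#' @param T temperature in K
#' @return scalar gE/(RT)
#' @export
excess_gibbs <- function(model, components, x, T) {
  E <- if (is.matrix(components)) components else embedding_matrix(components)
  gibbsnn_eval(model, E, x, T, need_hE = FALSE)$gE_RT
}

#' Activity coefficients of all components
#'
#' Evaluates the network and differentiates gE/(RT) with respect to the
#' independent mole fractions, giving Raoult-normalized log activity
#' coefficients that satisfy the Gibbs-Duhem equation by construction.
#'
#' @inheritParams excess_gibbs
#' @return list of class `gamma_result` with `ln_gamma` (length N),
#'   `gE_over_RT`, and a `subsystems` diagnostic table (projected fractions,
#'   similarity and interaction per binary subsystem)
#' @export
activity_coefficients <- function(model, components, x, T) {
  E <- if (is.matrix(components)) components else embedding_matrix(components)
  ev <- gibbsnn_eval(model, E, x, T, need_hE = FALSE)
  structure(list(ln_gamma = ev$ln_gamma, gE_over_RT = ev$gE_RT,
                 subsystems = ev$subsystems), class = "gamma_result")
}

#' Excess enthalpy of a mixture
#'
#' `hE = -(R T^2 / s_T) d(gE/RT)/dT*`, the chain rule accounting for the
#' temperature scaling of the network input.
#'
#' @inheritParams excess_gibbs
#' @return scalar hE in J/mol
#' @export
excess_enthalpy <- function(model, components, x, T) {
  E <- if (is.matrix(components)) components else embedding_matrix(components)
  gibbsnn_eval(model, E, x, T)$hE
}

#' Log activity coefficient at infinite dilution
#'
#' Evaluates the activity coefficients at a composition where the solute
#' fraction is exactly zero (the formulas stay finite on the simplex
#' boundary) and returns the solute entry.
#'
#' @inheritParams excess_gibbs
#' @param solute_index index of the infinitely diluted component
#' @param solvent_x mole fractions of the non-solute components (in the order
#'   they appear in `components` with the solute removed); must sum to 1
#' @return scalar ln(gamma_solute^infinity)
#' @export
ln_gamma_infinite_dilution <- function(model, components, solute_index,
                                       solvent_x, T) {
  E <- if (is.matrix(components)) components else embedding_matrix(components)
  N <- ncol(E)
  if (solute_index < 1L || solute_index > N) stop("solute_index out of range")
  stopifnot(length(solvent_x) == N - 1L)
  if (abs(sum(solvent_x) - 1) > 1e-9) stop("solvent fractions must sum to 1")
  x <- numeric(N)
  x[-solute_index] <- solvent_x
  gibbsnn_eval(model, E, x, T, need_hE = FALSE)$ln_gamma[solute_index]
}
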