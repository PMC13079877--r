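# Classical binary gE models used as ground truth for synthetic data and as
# analytic cross-checks: two-suffix Margules with A(T) = a + b/T, and NRTL
# with tau_ij(T) = a_ij + b_ij/T.  Each model is wrapped as a "gamma
# provider": a closed set of mutually consistent functions of (x1, T) for
# gE/RT, its first and second composition derivatives, ln gamma, and hE.

new_gamma_provider <- function(name, gE, dgE, d2gE, ln_gamma, hE = NULL,
                               pars = list()) {
  structure(list(name = name, gE = gE, dgE = dgE, d2gE = d2gE,
                 ln_gamma = ln_gamma, hE = hE, pars = pars),
            class = "gamma_provider")
}

#' Ideal-mixture provider
#'
#' @return a `gamma_provider` with gE = 0 and unit activity coefficients
#' @export
provider_ideal <- function() {
  z <- function(x1, T) rep(0, length(x1))
  new_gamma_provider("ideal", gE = z, dgE = z, d2gE = z,
                     ln_gamma = function(x1, T)
                       list(lng1 = rep(0, length(x1)), lng2 = rep(0, length(x1))),
                     hE = z)
}

#' Two-suffix Margules provider
#'
#' `gE/RT = A(T) x1 x2` with `A(T) = a + b/T`; `ln gamma_1 = A x2^2`,
#' `hE = R b x1 x2` (analytically consistent with the Gibbs-Helmholtz
#' relation).
#'
#' @param a dimensionless interaction offset
#' @param b temperature coefficient in K
#' @return a `gamma_provider`
#' @export
provider_margules <- function(a, b = 0) {
  A <- function(T) a + b / T
  new_gamma_provider("margules",
    gE   = function(x1, T) A(T) * x1 * (1 - x1),
    dgE  = function(x1, T) A(T) * (1 - 2 * x1),
    d2gE = function(x1, T) rep(-2 * A(T), length(x1)),
    ln_gamma = function(x1, T)
      list(lng1 = A(T) * (1 - x1)^2, lng2 = A(T) * x1^2),
    hE = function(x1, T) GAS_R * b * x1 * (1 - x1),
    pars = list(a = a, b = b))
}

#' NRTL provider
#'
#' Nonrandom two-liquid model with temperature-dependent interactions
#' `tau_ij(T) = a_ij + b_ij/T` and nonrandomness parameter `alpha` in
#' (0, 0.5].  All derivatives (composition and temperature) are closed form.
#'
#' @param a12,b12,a21,b21 interaction parameters (b in K)
#' @param alpha nonrandomness parameter
#' @return a `gamma_provider`
#' @export
provider_nrtl <- function(a12, b12, a21, b21, alpha = 0.3) {
  if (alpha <= 0 || alpha > 0.5) stop("alpha must be in (0, 0.5]")
  tau <- function(a, b, T) a + b / T
  parts <- function(x1, T) {
    t12 <- tau(a12, b12, T); t21 <- tau(a21, b21, T)
    G12 <- exp(-alpha * t12); G21 <- exp(-alpha * t21)
    x2 <- 1 - x1
    list(t12 = t12, t21 = t21, G12 = G12, G21 = G21,
         D1 = x1 + x2 * G21, D2 = x2 + x1 * G12, x2 = x2)
  }
  Ffun <- function(p) p$t21 * p$G21 / p$D1 + p$t12 * p$G12 / p$D2
  new_gamma_provider("nrtl",
    gE = function(x1, T) { p <- parts(x1, T); x1 * p$x2 * Ffun(p) },
    dgE = function(x1, T) {
      p <- parts(x1, T)
      Fp <- -p$t21 * p$G21 * (1 - p$G21) / p$D1^2 -
             p$t12 * p$G12 * (p$G12 - 1) / p$D2^2
      (1 - 2 * x1) * Ffun(p) + x1 * p$x2 * Fp
    },
    d2gE = function(x1, T) {
      p <- parts(x1, T)
      dD1 <- 1 - p$G21; dD2 <- p$G12 - 1
      Fp  <- -p$t21 * p$G21 * dD1 / p$D1^2 - p$t12 * p$G12 * dD2 / p$D2^2
      Fpp <- 2 * p$t21 * p$G21 * dD1^2 / p$D1^3 +
             2 * p$t12 * p$G12 * dD2^2 / p$D2^3
      -2 * Ffun(p) + 2 * (1 - 2 * x1) * Fp + x1 * p$x2 * Fpp
    },
    ln_gamma = function(x1, T) {
      p <- parts(x1, T)
      list(lng1 = p$x2^2 * (p$t21 * (p$G21 / p$D1)^2 + p$t12 * p$G12 / p$D2^2),
           lng2 = x1^2  * (p$t12 * (p$G12 / p$D2)^2 + p$t21 * p$G21 / p$D1^2))
    },
    hE = function(x1, T) {
      p <- parts(x1, T)
      dF_dt21 <- p$G21 * (1 - alpha * p$t21) / p$D1 +
                 alpha * p$t21 * p$x2 * p$G21^2 / p$D1^2
      dF_dt12 <- p$G12 * (1 - alpha * p$t12) / p$D2 +
                 alpha * p$t12 * x1 * p$G12^2 / p$D2^2
      dgdT <- x1 * p$x2 * (dF_dt21 * (-b21 / T^2) + dF_dt12 * (-b12 / T^2))
      -GAS_R * T^2 * dgdT
    },
    pars = list(a12 = a12, b12 = b12, a21 = a21, b21 = b21, alpha = alpha))
}

#' Provider backed by a trained network
#'
#' Wraps a `gibbsnn_network` (or a list of networks, averaged arithmetically,
#' which is equivalent to differentiating the mean gE surface since all
#' outputs are linear in gE and its derivatives) for a fixed binary pair.
#'
#' @param model a `gibbsnn_network` or list of them
#' @param components components frame (2 rows) or D x 2 embedding matrix
#' @return a `gamma_provider`
#' @export
provider_network <- function(model, components) {
  E <- if (is.matrix(components)) components else embedding_matrix(components)
  if (ncol(E) != 2L) stop("network provider requires a binary system")
  models <- if (inherits(model, "gibbsnn_network")) list(model) else model
  avg <- function(x1, T, what, need_d2 = FALSE, need_hE = FALSE) {
    vals <- lapply(models, function(m)
      gibbsnn_binary_eval(m, E, x1, T, need_d2 = need_d2, need_hE = need_hE)[[what]])
    Reduce(`+`, vals) / length(vals)
  }
  new_gamma_provider("network",
    gE   = function(x1, T) avg(x1, T, "g"),
    dgE  = function(x1, T) avg(x1, T, "dg"),
    d2gE = function(x1, T) avg(x1, T, "d2g", need_d2 = TRUE),
    ln_gamma = function(x1, T)
      list(lng1 = avg(x1, T, "ln_gamma1"), lng2 = avg(x1, T, "ln_gamma2")),
    hE = function(x1, T) avg(x1, T, "hE", need_hE = TRUE))
}

#' Antoine vapor pressure
#'
#' `log10(p_s / bar) = A - B / (T/K + C)`.
#'
#' @param coefs numeric vector `c(A, B, C)` or an n x 3 matrix (one row per
#'   component)
#' @param T temperature in K
#' @return vapor pressure(s) in bar
#' @export
antoine_psat <- function(coefs, T) {
  if (is.null(dim(coefs))) coefs <- matrix(coefs, nrow = 1L)
  10^(coefs[, 1L] - coefs[, 2L] / (T + coefs[, 3L]))
}
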