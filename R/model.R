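# The excess-Gibbs-energy network.
#
# Three feed-forward networks built from Lipschitz-constrained layers:
#   EmbeddingNetwork : 1 layer, D -> width          (+ SiLU)
#   MixtureNetwork   : 2 layers, width+2 -> width -> width (+ SiLU each)
#   PropertyNetwork  : 2 layers, width -> width (+ SiLU) -> 1 (linear scalar)
# The width is 96 in the reference configuration; the scalar head of the
# PropertyNetwork is forced by the binary interaction q_ij being a scalar.
# beta_rbf = 100 is fixed: only essentially identical refined embeddings
# reach similarity 1 and get lumped.

CHECKPOINT_VERSION <- "gibbsnn-1"

#' Construct an (untrained) excess-Gibbs-energy network
#'
#' @param D embedding dimension of the input components
#' @param width hidden width of all layers (96 in the reference setup)
#' @param beta_rbf RBF sharpness for the component similarity score (fixed
#'   at 100 in the reference setup)
#' @param scalers an `input_scalers` object (see [fit_scalers()]); a unit
#'   scaler is used if omitted
#' @param seed integer seed for the weight initialization
#' @return an object of class `gibbsnn_network`
#' @export
gibbsnn_network <- function(D = 16L, width = 96L, beta_rbf = 100,
                            scalers = NULL, seed = 1L) {
  if (is.null(scalers)) {
    scalers <- structure(list(t_mean = 0, t_std = 1,
                              emb_mean = rep(0, D), emb_std = rep(1, D)),
                         class = "input_scalers")
  }
  stopifnot(length(scalers$emb_mean) == D)
  layers <- with_seed(seed, list(
    emb   = new_lipschitz_layer(width, D),
    mix1  = new_lipschitz_layer(width, width + 2L),
    mix2  = new_lipschitz_layer(width, width),
    prop1 = new_lipschitz_layer(width, width),
    prop2 = new_lipschitz_layer(1L, width)
  ))
  structure(list(D = as.integer(D), width = as.integer(width),
                 beta_rbf = beta_rbf, layers = layers, scalers = scalers,
                 Weff = NULL, q_fun = NULL,
                 version = CHECKPOINT_VERSION),
            class = "gibbsnn_network")
}

#' A stub network with a prescribed binary interaction
#'
#' Replaces the learned interaction q_ij by a user-supplied function of the
#' projected mole fraction and the temperature.  Used to exercise the
#' surrounding thermodynamic machinery (lumping, projection, activity
#' coefficient assembly, excess-enthalpy chain rule) against closed forms.
#'
#' @param q_fun function `(X, T)` returning a list with elements `q`, `qX`,
#'   `qXX` (derivatives w.r.t. the projected fraction) and `qT` (derivative
#'   w.r.t. the real temperature in K); each the same length as `X`
#' @inheritParams gibbsnn_network
#' @return a `gibbsnn_network` whose interaction is `q_fun`
#' @examples
#' m <- gibbsnn_stub(constant_q(2))  # two-suffix Margules, A = 2
#' @export
gibbsnn_stub <- function(q_fun, D = 4L, scalers = NULL, seed = 1L) {
  m <- gibbsnn_network(D = D, width = 8L, scalers = scalers, seed = seed)
  m$q_fun <- q_fun
  m
}

#' @rdname gibbsnn_stub
#' @param A constant interaction value
#' @export
constant_q <- function(A) {
  force(A)
  function(X, T) list(q = rep(A, length(X)), qX = rep(0, length(X)),
                      qXX = rep(0, length(X)), qT = rep(0, length(X)))
}

#' @rdname gibbsnn_stub
#' @param A0,A1 interaction `q(T) = A0 + A1 / T` (A1 in K)
#' @export
temperature_q <- function(A0, A1) {
  force(A0); force(A1)
  function(X, T) list(q = rep(A0 + A1 / T, length(X)), qX = rep(0, length(X)),
                      qXX = rep(0, length(X)), qT = rep(-A1 / T^2, length(X)))
}

#' Freeze a network for prediction
#'
#' Computes converged effective (spectrally normalized) weights once and
#' stores them, so repeated predictions do not re-run power iteration.
#'
#' @param model a `gibbsnn_network`
#' @return the model with effective weights cached
#' @export
freeze_network <- function(model) {
  model$Weff <- lapply(model$layers, layer_effective, n_iter = 50L)
  model
}

network_weff <- function(model) {
  if (!is.null(model$Weff)) model$Weff
  else lapply(model$layers, layer_effective, n_iter = 50L)
}

# Flatten / restore trainable parameters (used by the optimizer and the
# checkpoint format).
network_params <- function(model) {
  ps <- list()
  for (nm in names(model$layers)) {
    ly <- model$layers[[nm]]
    ps[[paste0(nm, ".W")]] <- ly$W
    ps[[paste0(nm, ".b")]] <- ly$b
    ps[[paste0(nm, ".c")]] <- ly$c_star
  }
  ps
}

network_set_params <- function(model, ps) {
  for (nm in names(model$layers)) {
    model$layers[[nm]]$W <- ps[[paste0(nm, ".W")]]
    model$layers[[nm]]$b <- as.numeric(ps[[paste0(nm, ".b")]])
    model$layers[[nm]]$c_star <- as.numeric(ps[[paste0(nm, ".c")]])
  }
  model$Weff <- NULL
  model
}
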