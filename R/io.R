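# Checkpoints and run configuration.
#
# Checkpoints are versioned JSON holding all layer parameters, Lipschitz
# constants, power-iteration state, scalers and dimensions; loaders reject
# unknown format versions.  JSON keeps the deliverables plain text while
# round-tripping parameters to ~15 significant digits, which reproduces
# predictions far below any tolerance used in this package.

layer_to_list <- function(l) {
  list(W = l$W, b = l$b, c_star = l$c_star, u = l$u, v = l$v)
}

as_dbl_matrix <- function(W) {
  W <- as.matrix(W)
  storage.mode(W) <- "double"
  dimnames(W) <- NULL
  W
}

#' Save a model checkpoint
#'
#' Works for a single `gibbsnn_network`, a fitted `gibbsnn` ensemble, or a
#' `surrogate_network`.
#'
#' @param object the model
#' @param path output path (JSON)
#' @export
save_checkpoint <- function(object, path) {
  pack_network <- function(m) list(
    D = m$D, width = m$width, beta_rbf = m$beta_rbf,
    layers = lapply(m$layers, layer_to_list),
    scalers = unclass(m$scalers))
  obj <- if (inherits(object, "gibbsnn_network")) {
    list(version = CHECKPOINT_VERSION, kind = "network",
         network = pack_network(object))
  } else if (inherits(object, "gibbsnn")) {
    list(version = CHECKPOINT_VERSION, kind = "ensemble",
         members = lapply(object$members, pack_network),
         best_epoch = object$best_epoch,
         validation_systems = object$validation_systems)
  } else if (inherits(object, "surrogate_network")) {
    list(version = CHECKPOINT_VERSION, kind = "surrogate",
         n_grid = object$n_grid, hidden = object$hidden,
         layers = lapply(object$layers, function(l) list(W = l$W, b = l$b)))
  } else stop("unsupported object")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint path written by [save_checkpoint()]
#' @return the reconstructed model (networks come back frozen)
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$version, CHECKPOINT_VERSION))
    stop("unknown checkpoint version: ", obj$version)
  unpack_network <- function(nw) {
    sc <- structure(lapply(nw$scalers, as.numeric), class = "input_scalers")
    m <- gibbsnn_network(D = nw$D, width = nw$width, beta_rbf = nw$beta_rbf,
                         scalers = sc)
    for (nm in names(m$layers)) {
      li <- nw$layers[[nm]]
      m$layers[[nm]] <- list(W = as_dbl_matrix(li$W),
                             b = as.numeric(li$b),
                             c_star = as.numeric(li$c_star),
                             u = as.numeric(li$u), v = as.numeric(li$v))
    }
    freeze_network(m)
  }
  if (identical(obj$kind, "network")) {
    unpack_network(obj$network)
  } else if (identical(obj$kind, "ensemble")) {
    members <- lapply(obj$members, unpack_network)
    structure(list(members = members, scalers = members[[1L]]$scalers,
                   history = NULL, best_epoch = obj$best_epoch,
                   control = NULL,
                   validation_systems = obj$validation_systems,
                   D = members[[1L]]$D), class = "gibbsnn")
  } else if (identical(obj$kind, "surrogate")) {
    sm <- surrogate_network(n_grid = obj$n_grid, hidden = obj$hidden)
    for (nm in names(sm$layers)) {
      li <- obj$layers[[nm]]
      sm$layers[[nm]] <- list(W = as_dbl_matrix(li$W), b = as.numeric(li$b))
    }
    sm
  } else stop("unknown checkpoint kind: ", obj$kind)
}

RUN_CONFIG_KEYS <- list(
  model = c("width", "D", "beta_rbf"),
  train = c("epochs", "batch", "max_lr", "min_epoch", "n_ensemble", "seed",
            "weights", "weight_decay"),
  data = c("paths", "fold", "mode"))

#' Read and validate a run configuration (YAML)
#'
#' Known sections are `model`, `train`, `data`; unknown keys are rejected
#' with a schema message.
#'
#' @param path YAML file
#' @return nested configuration list
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad_sec <- setdiff(names(cfg), names(RUN_CONFIG_KEYS))
  if (length(bad_sec))
    stop("unknown config section(s): ", paste(bad_sec, collapse = ", "),
         " (expected: ", paste(names(RUN_CONFIG_KEYS), collapse = ", "), ")")
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), RUN_CONFIG_KEYS[[sec]])
    if (length(bad))
      stop(sprintf("unknown key(s) in '%s': %s (expected: %s)", sec,
                   paste(bad, collapse = ", "),
                   paste(RUN_CONFIG_KEYS[[sec]], collapse = ", ")))
  }
  cfg
}
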