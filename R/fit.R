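# The fitting function and the fitted-model class.

#' Control parameters for fitting
#'
#' @param width hidden width of all layers (96 in the reference setup;
#'   smaller widths are appropriate for small synthetic studies)
#' @param epochs training epochs
#' @param batch_size minibatch size (records of all types mixed
#'   proportionally by shuffling)
#' @param max_lr peak learning rate of the one-cycle schedule
#' @param min_epoch earliest epoch eligible for validation-based selection
#' @param n_ensemble number of ensemble members (independent weight
#'   initializations; the reference setup uses 10)
#' @param weights loss weights, see [total_loss()]; defaults
#'   `(w_TPX, w_LLE, w_HE, w_Gibbs, w_Lips) = (1, 5, 0.1, 0.1, 1e-6)`
#' @param weight_decay decoupled AdamW weight decay on the raw matrices
#' @param l2_lambda L2 coefficient used only when `w_Lips = 0`
#' @param n_grid composition grid for the LLE/Gibbs losses
#' @param seed integer seed
#' @return a list of class `gibbsnn_control`
#' @export
gibbsnn_control <- function(width = 96L, epochs = 200L, batch_size = 512L,
                            max_lr = 0.01, min_epoch = 50L, n_ensemble = 1L,
                            weights = default_loss_weights(),
                            weight_decay = 1e-2, l2_lambda = 1e-4,
                            n_grid = 101L, seed = 1L) {
  weights <- utils::modifyList(default_loss_weights(), as.list(weights))
  structure(list(width = as.integer(width), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), max_lr = max_lr,
                 min_epoch = as.integer(min_epoch),
                 n_ensemble = as.integer(n_ensemble), weights = weights,
                 weight_decay = weight_decay, l2_lambda = l2_lambda,
                 n_grid = as.integer(n_grid), seed = as.integer(seed)),
            class = "gibbsnn_control")
}

# Weighted validation data loss (model selection criterion): the five data
# losses, weighted as in the total loss, per validation record.
weighted_data_loss <- function(losses, weights, n) {
  (losses$TPXY + weights$w_TPX * losses$TPX + losses$ACI +
     weights$w_LLE * losses$LLE + weights$w_HE * losses$HE) / n
}

#' Fit a neural excess-Gibbs-energy model
#'
#' Trains an ensemble of Lipschitz-regularized networks on mixed
#' thermodynamic records by minimizing the weighted sum of the five data
#' losses, the Gibbs stability loss and the Lipschitz term, using AdamW with
#' a one-cycle schedule.  Input scalers are fitted on the training split
#' only.  For each member, the epoch (not earlier than `min_epoch`) with the
#' lowest weighted validation data loss is kept.
#'
#' @param records records data frame (see [generate_records()] /
#'   [read_records()]); binary systems
#' @param components components frame with embeddings (and Antoine
#'   coefficients for the VLE record types)
#' @param validation character vector of validation `system_id`s; when
#'   `NULL`, a 95/5 system-wise split is drawn with the control seed
#' @param surrogate a trained `surrogate_network`; required when LLE records
#'   are present (its weights stay frozen — gradients reach the main model
#'   only through the Gibbs-energy curve)
#' @param control a [gibbsnn_control()] list
#' @param verbose print one line per epoch
#' @return an object of class `gibbsnn`: fields `members` (frozen
#'   `gibbsnn_network`s), `scalers`, `history` (per-member, per-epoch loss
#'   table), `best_epoch`, `control`, `validation_systems`
#' @export
gibbsnn <- function(records, components, validation = NULL, surrogate = NULL,
                    control = gibbsnn_control(), verbose = FALSE) {
  stopifnot(inherits(control, "gibbsnn_control"))
  if (is.null(validation)) {
    sp <- split_systems(records, "full", seed = control$seed)
    validation <- sp$validation
  }
  is_val <- records$system_id %in% validation
  train_rec <- records[!is_val, , drop = FALSE]
  val_rec <- records[is_val, , drop = FALSE]
  if (!nrow(val_rec)) stop("validation set is empty")
  if (!nrow(train_rec)) stop("training set is empty")
  if (any(records$type == "LLE") && is.null(surrogate))
    stop("LLE records present: pass a pre-trained surrogate (train_surrogate)")

  scalers <- fit_scalers(train_rec, components)
  D <- sum(grepl("^emb_", names(components)))
  data_tr <- prepare_training_data(train_rec, components, scalers,
                                   n_grid = control$n_grid)
  data_va <- prepare_training_data(val_rec, components, scalers,
                                   n_grid = control$n_grid)

  n_tr <- nrow(train_rec)
  steps_per_epoch <- ceiling(n_tr / control$batch_size)
  total_steps <- steps_per_epoch * control$epochs
  decay_names <- paste0(c("emb", "mix1", "mix2", "prop1", "prop2"), ".W")

  members <- vector("list", control$n_ensemble)
  best_epochs <- integer(control$n_ensemble)
  history <- list()

  for (mem in seq_len(control$n_ensemble)) {
    model <- gibbsnn_network(D = D, width = control$width,
                             scalers = scalers,
                             seed = child_seed(control$seed,
                                               paste0("init-", mem)))
    params <- network_params(model)
    opt <- adam_init(params)
    step <- 0L
    best <- list(loss = Inf, params = params, epoch = NA_integer_)
    hist <- vector("list", control$epochs)
    with_seed(child_seed(control$seed, paste0("epochs-", mem)), {
      for (ep in seq_len(control$epochs)) {
        ord <- sample.int(n_tr)
        for (bi in seq_len(steps_per_epoch)) {
          rows <- ord[((bi - 1L) * control$batch_size + 1L):
                        min(bi * control$batch_size, n_tr)]
          step <- step + 1L
          lr <- one_cycle_lr(step, total_steps, control$max_lr)
          bl <- build_batch_losses(model, params, data_tr, rows, surrogate,
                                   control$weights, want_grad = TRUE,
                                   l2_lambda = control$l2_lambda)
          for (nm in names(bl$pi_states)) {   # persist warm-started state
            model$layers[[nm]]$u <- bl$pi_states[[nm]]$u
            model$layers[[nm]]$v <- bl$pi_states[[nm]]$v
          }
          tape_backward(bl$tape, bl$total)
          grads <- lapply(bl$pn, function(p) p$grad)
          params <- adam_step(params, grads, opt, lr,
                              weight_decay = control$weight_decay,
                              decay = decay_names)
        }
        model <- network_set_params(model, params)
        ev <- build_batch_losses(model, params, data_va,
                                 seq_len(nrow(val_rec)), surrogate,
                                 control$weights, want_grad = FALSE)
        vl <- weighted_data_loss(ev$losses, control$weights, nrow(val_rec))
        hist[[ep]] <- data.frame(member = mem, epoch = ep, val_loss = vl,
                                 t(unlist(ev$losses)))
        if (verbose)
          message(sprintf("member %d epoch %3d  val %.5f", mem, ep, vl))
        if (ep >= control$min_epoch && vl < best$loss)
          best <- list(loss = vl, params = params, epoch = ep)
      }
    })
    if (is.na(best$epoch))
      stop("no epoch reached min_epoch; increase epochs or lower min_epoch")
    model <- network_set_params(model, best$params)
    members[[mem]] <- freeze_network(model)
    best_epochs[mem] <- best$epoch
    history[[mem]] <- do.call(rbind, hist)
  }

  structure(list(members = members, scalers = scalers,
                 history = do.call(rbind, history),
                 best_epoch = best_epochs, control = control,
                 validation_systems = validation,
                 D = D), class = "gibbsnn")
}

#' @export
print.gibbsnn <- function(x, ...) {
  cat("Neural excess-Gibbs-energy model\n")
  cat(sprintf("  %d ensemble member(s), width %d, embedding dimension %d\n",
              length(x$members), x$control$width, x$D))
  cat(sprintf("  selected epoch(s): %s\n",
              paste(x$best_epoch, collapse = ", ")))
  fin <- x$history[x$history$epoch == max(x$history$epoch), ]
  cat(sprintf("  final validation data loss: %.5f\n", mean(fin$val_loss)))
  invisible(x)
}

#' @export
summary.gibbsnn <- function(object, ...) {
  h <- object$history
  out <- list(
    members = length(object$members),
    best_epoch = object$best_epoch,
    val_loss_first = mean(h$val_loss[h$epoch == 1L]),
    val_loss_best = mean(vapply(seq_along(object$members), function(m)
      min(h$val_loss[h$member == m & h$epoch >= object$control$min_epoch]),
      1)),
    lipschitz = vapply(object$members, lipschitz_loss, 1))
  class(out) <- "summary.gibbsnn"
  out
}

#' @export
print.summary.gibbsnn <- function(x, ...) {
  cat(sprintf("members: %d\n", x$members))
  cat(sprintf("validation data loss: epoch 1 %.5f -> best %.5f\n",
              x$val_loss_first, x$val_loss_best))
  cat(sprintf("Lipschitz bounds: %s\n",
              paste(sprintf("%.3g", x$lipschitz), collapse = ", ")))
  invisible(x)
}

#' @export
coef.gibbsnn <- function(object, ...) {
  do.call(rbind, lapply(seq_along(object$members), function(m) {
    ly <- object$members[[m]]$layers
    data.frame(member = m, layer = names(ly),
               lipschitz = vapply(ly, function(l) softplus(l$c_star), 1),
               row.names = NULL)
  }))
}

#' Predict activity coefficients and related properties
#'
#' Ensemble predictions at one state point.  Log activity coefficients,
#' gE/(RT) and hE are linear in the members' Gibbs-energy surfaces, so the
#' arithmetic mean over members equals differentiating the mean surface.
#'
#' @param object a fitted `gibbsnn` model
#' @param components components frame rows (or embedding matrix) in the
#'   order of `x`
#' @param x mole fractions
#' @param T temperature in K
#' @param what `"ln_gamma"`, `"gE_RT"` or `"hE"`
#' @param ... unused
#' @return numeric (length N for `"ln_gamma"`, scalar otherwise)
#' @export
predict.gibbsnn <- function(object, components, x, T,
                            what = c("ln_gamma", "gE_RT", "hE"), ...) {
  what <- match.arg(what)
  E <- if (is.matrix(components)) components else embedding_matrix(components)
  vals <- lapply(object$members, function(m) {
    ev <- gibbsnn_eval(m, E, x, T, need_hE = (what == "hE"))
    switch(what, ln_gamma = ev$ln_gamma, gE_RT = ev$gE_RT, hE = ev$hE)
  })
  Reduce(`+`, vals) / length(vals)
}

#' @rdname predict.gibbsnn
#' @export
predict.gibbsnn_network <- function(object, components, x, T,
                                    what = c("ln_gamma", "gE_RT", "hE"), ...) {
  fit <- structure(list(members = list(object)), class = "gibbsnn")
  predict(fit, components, x, T, what = what)
}
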