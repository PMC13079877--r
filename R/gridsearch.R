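# Loss-weight grid search.
#
# The relative weighting of the data, stability and regularization losses is
# the main free hyperparameter of the training procedure.  This harness
# trains one model per weight combination on a synthetic dataset and scores
# each by the weighted validation data loss plus diagnostic quality measures
# (held-out accuracy and miscibility-gap detection on the training systems).

#' Grid search over loss weights
#'
#' @param grid data frame with columns among `w_TPX`, `w_LLE`, `w_HE`,
#'   `w_Gibbs`, `w_Lips` (missing columns keep their defaults); one row per
#'   candidate
#' @param seed master seed for the synthetic dataset and training
#' @param n_systems,width,epochs,batch_size,min_epoch study configuration
#' @return the grid with appended columns `val_loss` (best weighted
#'   validation data loss), `mae_ln_gamma` (held-out state points of the
#'   training systems), `detection_rate` and `val_loss_drop`
#' @export
grid_search_weights <- function(grid, seed = 1L, n_systems = 60L,
                                width = 32L, epochs = 100L,
                                batch_size = 128L, min_epoch = 25L) {
  out <- grid
  out$val_loss <- NA_real_; out$mae_ln_gamma <- NA_real_
  out$detection_rate <- NA_real_; out$val_loss_drop <- NA_real_
  ds <- synthetic_dataset(n_systems, seed = child_seed(seed, "data"))
  lab <- surrogate_training_curves(2000L, seed = child_seed(seed, "curves"))
  sm <- train_surrogate(lab, seed = child_seed(seed, "surrogate"))
  for (i in seq_len(nrow(grid))) {
    w <- utils::modifyList(default_loss_weights(),
                           as.list(grid[i, intersect(names(grid),
                                                     names(default_loss_weights())),
                                        drop = FALSE]))
    res <- recovery_experiment(seed = seed, n_systems = n_systems,
                               width = width, epochs = epochs,
                               batch_size = batch_size,
                               min_epoch = min_epoch, surrogate = sm,
                               weights = w)
    h <- res$fit$history
    out$val_loss[i] <- min(h$val_loss[h$epoch >= min_epoch])
    out$mae_ln_gamma[i] <- res$mae_ln_gamma
    out$detection_rate[i] <- res$detection_rate
    out$val_loss_drop[i] <- res$val_loss_drop
  }
  out
}
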