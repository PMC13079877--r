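# The scaled-down parameter-recovery study.
#
# A desk-scale version of the full training pipeline on synthetic data with
# known ground truth: 60 embedding-linked binary systems (40% in the
# demixing regime), hidden width 32, embedding dimension 16, 100 epochs at
# batch size 128.  The study measures how well the trained model recovers
# the ground-truth activity-coefficient surfaces at held-out state points of
# the training systems, whether it detects the miscibility gaps, and how far
# the weighted validation data loss falls from the first epoch.

#' Run the parameter-recovery study
#'
#' Generates the synthetic dataset, trains the surrogate solver on labeled
#' classical-model curves, trains the main model, and evaluates (a) the mean
#' absolute error of ln gamma on freshly drawn noise-free state points of
#' the training systems, (b) the miscibility-gap detection rate on the
#' demixing training systems at their LLE record temperatures, and (c) the
#' relative drop of the weighted validation data loss.
#'
#' @param seed integer master seed; every random draw derives from it
#' @param n_systems number of synthetic binary systems
#' @param miscibility_mix fraction of demixing systems
#' @param width,epochs,batch_size,min_epoch training configuration
#' @param surrogate optional pre-trained surrogate (trained internally on
#'   2000 labeled curves when omitted)
#' @param weights loss weights (see [total_loss()])
#' @param n_ensemble number of ensemble members
#' @param verbose print training progress
#' @return list with `mae_ln_gamma`, `detection_rate`, `val_loss_drop`,
#'   `surrogate_val_mae`, `n_records`, plus the `fit`, `dataset` and
#'   `evaluation` objects
#' @export
recovery_experiment <- function(seed = 1L, n_systems = 60L,
                                miscibility_mix = 0.4, width = 32L,
                                epochs = 100L, batch_size = 128L,
                                min_epoch = 50L, surrogate = NULL,
                                weights = default_loss_weights(),
                                n_ensemble = 1L, verbose = FALSE) {
  ds <- synthetic_dataset(n_systems, seed = child_seed(seed, "data"),
                          miscibility_mix = miscibility_mix)
  if (is.null(surrogate)) {
    lab <- surrogate_training_curves(2000L, seed = child_seed(seed, "curves"))
    surrogate <- train_surrogate(lab, seed = child_seed(seed, "surrogate"))
  }
  ctl <- gibbsnn_control(width = width, epochs = epochs,
                         batch_size = batch_size, min_epoch = min_epoch,
                         weights = weights, n_ensemble = n_ensemble,
                         seed = child_seed(seed, "train"))
  # 10% of systems to validation, stratified by demixing status: at this
  # study size a larger-than-5% validation set keeps the selection metric
  # from being dominated by a single system
  validation <- with_seed(child_seed(seed, "valsplit"), {
    dem <- ds$systems$system_id[ds$systems$demixing]
    mis <- ds$systems$system_id[!ds$systems$demixing]
    c(sample(dem, max(1L, round(0.1 * length(dem)))),
      sample(mis, max(1L, round(0.1 * length(mis)))))
  })
  fit <- gibbsnn(ds$records, ds$components, validation = validation,
                 surrogate = surrogate, control = ctl, verbose = verbose)

  h <- fit$history
  v1 <- mean(h$val_loss[h$epoch == 1L])
  vbest <- mean(vapply(unique(h$member), function(m)
    min(h$val_loss[h$member == m & h$epoch >= min_epoch]), 1))
  train_sys <- setdiff(ds$systems$system_id, fit$validation_systems)

  # held-out, noise-free state points of the training systems
  zero <- list(ln_gamma = 0, x_lle = 0, hE = 0, ln_p = 0, y = 0)
  held_out <- do.call(rbind, lapply(
    which(ds$systems$system_id %in% train_sys), function(k)
      generate_records(ds$systems[k, ], ds$components,
                       counts = list(tpxy = 6, tpx = 0, aci = 0, lle = 0,
                                     he = 0),
                       noise = zero, seed = child_seed(seed, 10000L + k))))
  ev <- evaluate_records(fit, held_out, ds$components)
  mae <- mean(ev$mae$per_system$mae_sys[ev$mae$per_system$type == "TPXY"])

  dem <- intersect(ds$systems$system_id[ds$systems$demixing], train_sys)
  lle <- ds$records[ds$records$type == "LLE" & ds$records$system_id %in% dem, ,
                    drop = FALSE]
  det <- evaluate_records(fit, lle, ds$components)$detection_rate

  list(mae_ln_gamma = mae, detection_rate = det,
       val_loss_drop = 1 - vbest / v1,
       surrogate_val_mae = attr(surrogate, "val_mae"),
       n_records = nrow(ds$records),
       fit = fit, dataset = ds, evaluation = ev)
}
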