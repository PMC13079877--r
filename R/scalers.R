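# Standard scaling of the network inputs (temperature and embeddings).
#
# Scalers are fitted on the training split only; the stored temperature
# standard deviation s_T is needed again by the excess-enthalpy chain rule,
# hE = -(R T^2 / s_T) d(gE/RT)/dT*.

#' Fit input scalers on a training set
#'
#' Computes per-dimension mean/standard deviation of the embeddings of the
#' components that appear in the training records, and mean/sd of the
#' training temperatures.  Sample standard deviation (ddof = 1) is used, and
#' standard deviations are floored at 1e-8 so constant dimensions scale to 0
#' instead of dividing by zero.
#'
#' @param training_records records data frame (see [generate_records()]);
#'   must have columns `T_K` and `component_ids`
#' @param components components data frame with `emb_*` columns
#' @return an object of class `input_scalers` with fields `t_mean`, `t_std`,
#'   `emb_mean`, `emb_std`
#' @export
fit_scalers <- function(training_records, components) {
  if (nrow(training_records) == 0L) stop("training set is empty")
  ids <- unique(unlist(strsplit(training_records$component_ids, ";", fixed = TRUE)))
  E <- embedding_matrix(components)
  miss <- setdiff(ids, colnames(E))
  if (length(miss)) stop("components missing from frame: ", paste(miss, collapse = ", "))
  E <- E[, ids, drop = FALSE]
  tt <- training_records$T_K
  sd1 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  structure(list(
    t_mean = mean(tt),
    t_std = max(sd1(tt), 1e-8),
    emb_mean = rowMeans(E),
    emb_std = pmax(apply(E, 1L, sd1), 1e-8)
  ), class = "input_scalers")
}

scale_temperature <- function(scalers, T) (T - scalers$t_mean) / scalers$t_std

unscale_temperature <- function(scalers, Tstar) Tstar * scalers$t_std + scalers$t_mean

# E: D x n matrix (or length-D vector).
scale_embeddings <- function(scalers, E) {
  if (is.matrix(E)) (E - scalers$emb_mean) / scalers$emb_std
  else (E - scalers$emb_mean) / scalers$emb_std
}

unscale_embeddings <- function(scalers, Estar) {
  if (is.matrix(Estar)) Estar * scalers$emb_std + scalers$emb_mean
  else Estar * scalers$emb_std + scalers$emb_mean
}
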