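# System-wise data splitting.
#
# All records of a system (unordered set of its component ids) always land
# in the same set, so no state point of a test system is ever seen in
# training.  The ten-fold mode stratifies by the combination of data types a
# system has, dealing systems of each signature round-robin across folds so
# every fold carries a similar share of each data type.

#' Split a dataset system-wise
#'
#' @param records records data frame with `system_id` and `type`
#' @param mode `"tenfold"` (stratified cross-validation folds; within each
#'   fold the remaining systems are split 90/10 into train/validation) or
#'   `"full"` (95/5 train/validation, no test set)
#' @param seed integer seed
#' @param n_folds number of folds for `"tenfold"`
#' @return for `"tenfold"`: list with `assignment` (data frame `system_id`,
#'   `test_fold`) and `folds` (per fold, character vectors `train`,
#'   `validation`, `test`); for `"full"`: list with `train`, `validation`
#' @export
split_systems <- function(records, mode = c("tenfold", "full"), seed = 1L,
                          n_folds = 10L) {
  mode <- match.arg(mode)
  sys <- unique(records$system_id)
  sig <- vapply(sys, function(s)
    paste(sort(unique(records$type[records$system_id == s])), collapse = "+"),
    "")
  if (mode == "full") {
    res <- with_seed(child_seed(seed, "split-full"), {
      # 5% of systems to validation, allocated across the type-signature
      # strata by largest remainders
      groups <- split(seq_along(sys), sig)
      target <- max(1L, round(0.05 * length(sys)))
      quota <- vapply(groups, length, 1L) * 0.05
      k <- pmin(floor(quota), vapply(groups, length, 1L))
      need <- target - sum(k)
      if (need > 0) {
        extra <- order(quota - k, decreasing = TRUE)[seq_len(need)]
        k[extra] <- k[extra] + 1L
      }
      assign_val <- unlist(Map(function(ix, kk) {
        ix <- ix[sample.int(length(ix))]
        if (kk > 0) ix[seq_len(kk)] else integer(0)
      }, groups, k), use.names = FALSE)
      list(train = sys[-assign_val], validation = sys[assign_val])
    })
    if (!length(res$train)) stop("no training systems left")
    return(res)
  }
  if (length(sys) < n_folds) stop("fewer systems than folds")
  fold_of <- integer(length(sys))
  with_seed(child_seed(seed, "split-tenfold"), {
    off <- 0L
    for (ix in split(seq_along(sys), sig)) {
      ix <- ix[sample.int(length(ix))]
      fold_of[ix] <- ((off + seq_along(ix) - 1L) %% n_folds) + 1L
      off <- off + length(ix)
    }
    folds <- lapply(seq_len(n_folds), function(f) {
      test <- sys[fold_of == f]
      rest <- sys[fold_of != f]
      rsig <- sig[fold_of != f]
      val_ix <- unlist(lapply(split(seq_along(rest), rsig), function(jx) {
        jx <- jx[sample.int(length(jx))]
        jx[seq_along(jx) %% 10L == 0L]
      }), use.names = FALSE)
      if (!length(val_ix)) val_ix <- sample(seq_along(rest), 1L)
      list(train = rest[-val_ix], validation = rest[val_ix], test = test)
    })
    list(assignment = data.frame(system_id = sys, test_fold = fold_of),
         folds = folds)
  })
}
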