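# Per-record error metrics, system-wise aggregation, and miscibility-gap
# detection rates.

#' Error of a single prediction
#'
#' Type-specific absolute deviations: mean |Delta ln gamma| over the
#' components for VLE records with vapor composition, |Delta ln p| for
#' total-pressure records, |Delta ln gamma_inf| of the diluted solute for
#' infinite-dilution records, mean absolute deviation of the phase
#' compositions for LLE, and |Delta hE| in kJ/mol for excess enthalpies.
#'
#' @param record one record (one-row data frame or list) with a `type` tag
#' @param prediction type-dependent: `ln_gamma` vector (TPXY), `p` in bar
#'   (TPX), `ln_gamma_inf` (ACI), list with `x1_prime`/`x1_doubleprime`
#'   (LLE; only reported phases enter), `hE` in J/mol (HE)
#' @return nonnegative scalar error
#' @export
record_error <- function(record, prediction) {
  if (is.data.frame(record)) record <- as.list(record[1L, ])
  switch(record$type,
    TPXY = {
      tr <- record$ln_gamma_true
      if (is.null(tr)) stop("TPXY record needs reference ln_gamma_true")
      mean(abs(prediction$ln_gamma - tr))
    },
    TPX = abs(log(prediction$p) - log(record$p_bar)),
    ACI = abs(prediction$ln_gamma_inf - record$ln_gamma_inf),
    LLE = {
      terms <- numeric(0)
      if (!is.na(record$x1p)) {
        dp1 <- abs(prediction$x1_prime - record$x1p)
        terms <- c(terms, dp1, dp1)  # both components deviate equally (binary)
      }
      if (!is.na(record$x1pp)) {
        dp2 <- abs(prediction$x1_doubleprime - record$x1pp)
        terms <- c(terms, dp2, dp2)
      }
      if (!length(terms)) stop("LLE record reports no phase")
      sum(terms) / (2 * 2)  # 1/(2N) with N = 2, both phases
    },
    HE = abs(prediction$hE - record$hE_J_mol) / 1000,
    stop("unknown record type: ", record$type))
}

#' System-wise mean absolute errors
#'
#' Averages the per-record errors over all records of each (system, type),
#' then summarizes across systems with mean and median — so systems with
#' many data points do not dominate.
#'
#' @param errors data frame with columns `system_id`, `type`, `eps`
#' @return list with `per_system` (data frame `system_id, type, mae_sys,
#'   n`) and `overall` (data frame `type, mean_mae_sys, median_mae_sys,
#'   n_systems`)
#' @export
mae_sys <- function(errors) {
  if (!nrow(errors)) {
    return(list(per_system = data.frame(system_id = character(0),
                                        type = character(0),
                                        mae_sys = numeric(0), n = integer(0)),
                overall = data.frame(type = character(0),
                                     mean_mae_sys = numeric(0),
                                     median_mae_sys = numeric(0),
                                     n_systems = integer(0))))
  }
  agg <- stats::aggregate(eps ~ system_id + type, errors, mean)
  cnt <- stats::aggregate(eps ~ system_id + type, errors, length)
  per_system <- data.frame(system_id = agg$system_id, type = agg$type,
                           mae_sys = agg$eps, n = cnt$eps)
  ov <- do.call(rbind, lapply(split(per_system, per_system$type), function(d)
    data.frame(type = d$type[1L], mean_mae_sys = mean(d$mae_sys),
               median_mae_sys = stats::median(d$mae_sys),
               n_systems = nrow(d))))
  rownames(ov) <- NULL
  list(per_system = per_system, overall = ov)
}

#' Miscibility-gap detection rate
#'
#' Fraction of LLE systems for which the model predicts a phase split at the
#' recorded state points.  Detection is counted per record (gap predicted at
#' that temperature or not) and aggregated per system by majority.
#'
#' @param lle_records LLE records data frame
#' @param predicted logical vector, one entry per record: gap predicted
#' @return fraction in `[0, 1]` (NaN when no LLE systems)
#' @export
detection_rate <- function(lle_records, predicted) {
  stopifnot(nrow(lle_records) == length(predicted))
  per_sys <- tapply(predicted, lle_records$system_id,
                    function(v) mean(v) >= 0.5)
  mean(per_sys)
}

#' Evaluate a fitted model on a record set
#'
#' Produces per-record predictions and errors for all five record types,
#' system-wise aggregation, and the LLE detection tally.  For TPXY records a
#' `ln_gamma_true` reference is derived from the recorded (p, y, x) via the
#' extended Raoult's law, matching how the training targets are defined.
#'
#' @param fit a `gibbsnn` fit (or a single `gibbsnn_network`)
#' @param records records data frame
#' @param components components frame
#' @param n_grid grid used for LLE detection/prediction
#' @return list with `errors` (per evaluable record), `mae` (see
#'   [mae_sys()]), `lle_detection` (data frame per LLE record) and
#'   `detection_rate`
#' @export
evaluate_records <- function(fit, records, components, n_grid = 101L) {
  members <- if (inherits(fit, "gibbsnn")) fit$members else list(fit)
  E <- embedding_matrix(components)
  ant <- if (all(c("antoine_a", "antoine_b", "antoine_c") %in% names(components)))
    as.matrix(components[, c("antoine_a", "antoine_b", "antoine_c")]) else NULL
  if (!is.null(ant)) rownames(ant) <- components$component_id

  errs <- list(); det <- list()
  for (k in seq_len(nrow(records))) {
    rec <- as.list(records[k, ])
    ids <- strsplit(rec$component_ids, ";")[[1]]
    Ek <- E[, ids, drop = FALSE]
    x1 <- rec$x1
    pred_lng <- function(x1v) {
      vals <- lapply(members, function(m) {
        ev <- gibbsnn_binary_eval(m, Ek, x1v, rec$T_K)
        cbind(ev$ln_gamma1, ev$ln_gamma2)
      })
      Reduce(`+`, vals) / length(vals)
    }
    eps <- NA_real_
    if (rec$type == "TPXY") {
      ps <- c(antoine_psat(ant[ids[1L], ], rec$T_K),
              antoine_psat(ant[ids[2L], ], rec$T_K))
      rec$ln_gamma_true <- log(c(rec$p_bar * rec$y1 / (ps[1L] * rec$x1),
                                 rec$p_bar * rec$y2 / (ps[2L] * rec$x2)))
      lg <- pred_lng(x1)
      eps <- record_error(rec, list(ln_gamma = as.numeric(lg)))
    } else if (rec$type == "TPX") {
      lg <- pred_lng(x1)
      ps <- c(antoine_psat(ant[ids[1L], ], rec$T_K),
              antoine_psat(ant[ids[2L], ], rec$T_K))
      p <- ps[1L] * rec$x1 * exp(lg[1L]) + ps[2L] * rec$x2 * exp(lg[2L])
      eps <- record_error(rec, list(p = p))
    } else if (rec$type == "ACI") {
      lg <- pred_lng(if (rec$solute_idx == 1L) 0 else 1)
      eps <- record_error(rec, list(ln_gamma_inf = lg[rec$solute_idx]))
    } else if (rec$type == "HE") {
      vals <- vapply(members, function(m)
        gibbsnn_binary_eval(m, Ek, x1, rec$T_K, need_hE = TRUE)$hE, 1)
      eps <- record_error(rec, list(hE = mean(vals)))
    } else if (rec$type == "LLE") {
      pv <- provider_network(members, Ek)
      gaps <- cem_binary(gmix_curve(pv, rec$T_K, n_grid))
      found <- nrow(gaps) > 0L
      det[[length(det) + 1L]] <- data.frame(row = k,
                                            system_id = rec$system_id,
                                            T_K = rec$T_K, detected = found)
      if (found) {
        gi <- which.max(gaps$x1_doubleprime - gaps$x1_prime)
        eps <- record_error(rec, list(x1_prime = gaps$x1_prime[gi],
                                      x1_doubleprime = gaps$x1_doubleprime[gi]))
      }
    }
    if (!is.na(eps))
      errs[[length(errs) + 1L]] <- data.frame(row = k,
                                              system_id = rec$system_id,
                                              type = rec$type, eps = eps)
  }
  errors <- if (length(errs)) do.call(rbind, errs) else
    data.frame(row = integer(0), system_id = character(0),
               type = character(0), eps = numeric(0))
  lle_det <- if (length(det)) do.call(rbind, det) else
    data.frame(row = integer(0), system_id = character(0), T_K = numeric(0),
               detected = logical(0))
  dr <- if (nrow(lle_det))
    detection_rate(lle_det, lle_det$detected) else NaN
  list(errors = errors, mae = mae_sys(errors), lle_detection = lle_det,
       detection_rate = dr)
}
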