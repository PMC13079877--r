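# Training losses.
#
# Five data losses (VLE with vapor composition, total-pressure VLE,
# infinite dilution, LLE through the frozen surrogate, excess enthalpy), a
# Gibbs stability loss that penalizes missed miscibility gaps, and the
# Lipschitz regularization.  All data losses use the smooth-L1 function with
# a per-type transition parameter beta.  The losses are assembled on the
# autodiff tape; the exported numeric wrappers below evaluate them without
# gradients.

#' Smooth-L1 (Huber-like) loss values
#'
#' Elementwise `0.5 d^2/beta` for `|d| < beta`, else `|d| - beta/2`, with
#' `d = pred - target`.
#'
#' @param pred,target numeric
#' @param beta transition point (> 0)
#' @return elementwise loss values (callers apply their own reduction)
#' @export
smooth_l1 <- function(pred, target, beta) {
  stopifnot(beta > 0)
  d <- pred - target
  ifelse(abs(d) < beta, 0.5 * d^2 / beta, abs(d) - 0.5 * beta)
}

# Per-type smooth-L1 transition parameters.
SL1_BETA <- c(TPXY = 1.0, ACI = 2.0, TPX = 1.0, LLE = 0.35, HE = 2.0)

#' Total training loss
#'
#' `(L_TPXY + w_TPX L_TPX + L_ACI + w_LLE L_LLE + w_HE L_HE + w_Gibbs
#' L_Gibbs + w_Lips L_Lips) / N_b`.
#'
#' @param losses named list/vector with elements `TPXY`, `TPX`, `ACI`,
#'   `LLE`, `HE`, `Gibbs`, `Lips`
#' @param weights named vector with `w_TPX`, `w_LLE`, `w_HE`, `w_Gibbs`,
#'   `w_Lips` (all nonnegative)
#' @param N_b batch size (> 0)
#' @return scalar total loss
#' @export
total_loss <- function(losses, weights, N_b) {
  stopifnot(N_b > 0)
  if (any(unlist(weights) < 0)) stop("loss weights must be nonnegative")
  l <- as.list(losses); w <- as.list(weights)
  (l$TPXY + w$w_TPX * l$TPX + l$ACI + w$w_LLE * l$LLE + w$w_HE * l$HE +
     w$w_Gibbs * l$Gibbs + w$w_Lips * l$Lips) / N_b
}

#' Lipschitz regularization term
#'
#' Product over all layers of all three networks of `softplus(c*_l)` — the
#' model's (loose) Lipschitz bound, ignoring activation constants.
#'
#' @param model a `gibbsnn_network`
#' @return scalar
#' @export
lipschitz_loss <- function(model) {
  prod(vapply(model$layers, function(l) softplus(l$c_star), 1))
}

default_loss_weights <- function() {
  list(w_TPX = 1, w_LLE = 5, w_HE = 0.1, w_Gibbs = 0.1, w_Lips = 1e-6)
}

## ---- data preparation ------------------------------------------------------

# Turn a records data frame + components frame into the indexed structure the
# tape forward consumes.  Targets and everything independent of the model
# parameters (vapor pressures, scaled temperatures, grid constants) are
# precomputed here.
prepare_training_data <- function(records, components, scalers,
                                  n_grid = 101L) {
  E <- embedding_matrix(components)
  cid <- colnames(E)
  ant <- if (all(c("antoine_a", "antoine_b", "antoine_c") %in% names(components)))
    as.matrix(components[, c("antoine_a", "antoine_b", "antoine_c")]) else NULL
  if (!is.null(ant)) rownames(ant) <- components$component_id

  sys_ids <- unique(records$system_id)
  sys_comp <- do.call(rbind, lapply(sys_ids, function(s) {
    ids <- strsplit(records$component_ids[match(s, records$system_id)], ";")[[1]]
    if (length(ids) != 2L) stop("training supports binary systems; system ",
                                s, " has ", length(ids), " components")
    match(ids, cid)
  }))
  if (any(is.na(sys_comp))) stop("records reference unknown components")
  sys <- data.frame(system_id = sys_ids, ia = sys_comp[, 1L], ib = sys_comp[, 2L])

  recs <- records
  rownames(recs) <- seq_len(nrow(recs))
  recs$sysidx <- match(recs$system_id, sys_ids)
  recs$ia <- sys$ia[recs$sysidx]
  recs$ib <- sys$ib[recs$sysidx]
  recs$Tstar <- scale_temperature(scalers, recs$T_K)

  bytype <- split(seq_len(nrow(recs)), recs$type)
  get <- function(tp) if (is.null(bytype[[tp]])) recs[0, ] else recs[bytype[[tp]], ]

  tpxy <- get("TPXY")
  if (nrow(tpxy)) {
    if (is.null(ant)) stop("TPXY records need Antoine coefficients in the components frame")
    ps1 <- antoine_psat(ant[cid[tpxy$ia], , drop = FALSE], tpxy$T_K)
    ps2 <- antoine_psat(ant[cid[tpxy$ib], , drop = FALSE], tpxy$T_K)
    tpxy$t_lng1 <- log(tpxy$p_bar * tpxy$y1 / (ps1 * tpxy$x1))
    tpxy$t_lng2 <- log(tpxy$p_bar * tpxy$y2 / (ps2 * tpxy$x2))
  }
  tpx <- get("TPX")
  if (nrow(tpx)) {
    if (is.null(ant)) stop("TPX records need Antoine coefficients in the components frame")
    tpx$ps1 <- antoine_psat(ant[cid[tpx$ia], , drop = FALSE], tpx$T_K)
    tpx$ps2 <- antoine_psat(ant[cid[tpx$ib], , drop = FALSE], tpx$T_K)
    tpx$t_lnp <- log(tpx$p_bar)
  }
  aci <- get("ACI")
  if (nrow(aci)) aci$x1 <- ifelse(aci$solute_idx == 1L, 0, 1)
  he <- get("HE")
  lle <- get("LLE")

  list(E = E, Estar = scale_embeddings(scalers, E), sys = sys, records = recs,
       tpxy = tpxy, tpx = tpx, aci = aci, he = he, lle = lle,
       n_grid = n_grid, xgrid = seq(0, 1, length.out = n_grid))
}

## ---- tape assembly ---------------------------------------------------------

# Jet propagation on the tape (mirrors jet_linear/jet_silu in forward.R).
tape_jet_linear <- function(tape, W, b, J) {
  list(v = t_add(tape, t_mm(tape, W, J$v), b),
       dX = if (is.null(J$dX)) NULL else t_mm(tape, W, J$dX),
       dT = if (is.null(J$dT)) NULL else t_mm(tape, W, J$dT),
       d2X = if (is.null(J$d2X)) NULL else t_mm(tape, W, J$d2X))
}

tape_jet_silu <- function(tape, J) {
  f1 <- t_silu(tape, J$v, 1L)
  d2 <- NULL
  if (!is.null(J$dX)) {
    dd <- t_emul(tape, t_silu(tape, J$v, 2L), t_emul(tape, J$dX, J$dX))
    d2 <- if (is.null(J$d2X)) dd else t_add(tape, t_emul(tape, f1, J$d2X), dd)
  }
  list(v = t_silu(tape, J$v, 0L),
       dX = if (is.null(J$dX)) NULL else t_emul(tape, f1, J$dX),
       dT = if (is.null(J$dT)) NULL else t_emul(tape, f1, J$dT),
       d2X = d2)
}

tape_jet_add <- function(tape, A, B) {
  s0 <- function(a, b) if (is.null(a)) b else if (is.null(b)) a
        else t_add(tape, a, b)
  list(v = t_add(tape, A$v, B$v), dX = s0(A$dX, B$dX), dT = s0(A$dT, B$dT),
       d2X = s0(A$d2X, B$d2X))
}

# Deep-set interaction jets on the tape for a batch of binary records.
# theta: node (width x C); s_row: node (1 x S); returns 1 x n rows
# q, qd1 (= dq/dX), qd2, qTs (= dq/dT*), plus s_rec.
tape_q_jets <- function(tape, ctx, ia, ib, sysidx, X1node, X2node, Tstar,
                        need_d2 = FALSE, need_dT = FALSE) {
  n <- length(ia)
  w <- ctx$width
  s_rec <- t_cols(tape, ctx$s_row, sysidx)
  Trow <- matrix(Tstar, 1L, n)
  dX1 <- matrix(0, w + 2L, n); dX1[w + 1L, ] <- 1
  dX2 <- matrix(0, w + 2L, n); dX2[w + 1L, ] <- -1
  dT <- NULL
  if (need_dT) { dT <- matrix(0, w + 2L, n); dT[w + 2L, ] <- 1 }
  branch <- function(th_idx, Xn, dX) {
    J <- list(v = t_rbind(tape, list(t_cols(tape, ctx$theta, th_idx), Xn, Trow)),
              dX = dX, dT = dT, d2X = NULL)
    J <- tape_jet_silu(tape, tape_jet_linear(tape, ctx$Weff$mix1, ctx$pn[["mix1.b"]], J))
    tape_jet_silu(tape, tape_jet_linear(tape, ctx$Weff$mix2, ctx$pn[["mix2.b"]], J))
  }
  J <- tape_jet_add(tape, branch(ia, X1node, dX1), branch(ib, X2node, dX2))
  if (!need_d2) J$d2X <- NULL
  J <- tape_jet_silu(tape, tape_jet_linear(tape, ctx$Weff$prop1, ctx$pn[["prop1.b"]], J))
  J <- tape_jet_linear(tape, ctx$Weff$prop2, ctx$pn[["prop2.b"]], J)
  list(q = t_emul(tape, s_rec, J$v),
       qd1 = t_emul(tape, s_rec, J$dX),
       qd2 = if (need_d2) t_emul(tape, s_rec, J$d2X) else NULL,
       qTs = if (need_dT) t_emul(tape, s_rec, J$dT) else NULL,
       s_rec = s_rec)
}

# ln gamma rows for a batch of binary records at compositions x1 (constant).
tape_ln_gamma <- function(tape, jets, x1) {
  n <- length(x1)
  x1r <- matrix(x1, 1L); x2r <- matrix(1 - x1, 1L)
  pre <- x1r * x2r
  g <- t_emul(tape, pre, jets$q)
  dg <- t_add(tape,
              t_emul(tape, matrix(1 - 2 * x1, 1L), jets$q),
              t_emul(tape, t_emul(tape, pre, jets$s_rec), jets$qd1))
  list(g = g,
       lng1 = t_add(tape, g, t_emul(tape, x2r, dg)),
       lng2 = t_sub(tape, g, t_emul(tape, x1r, dg)),
       dg = dg)
}

# Build every loss term for one batch on a fresh tape.  `params` is the
# named parameter list; set want_grad = FALSE for evaluation-only passes.
build_batch_losses <- function(model, params, data, rows, surrogate,
                               weights, want_grad = TRUE,
                               l2_lambda = 1e-4, pi_iter = 2L) {
  tape <- new_tape(8192L)
  mk <- if (want_grad) t_param else t_const
  pn <- lapply(params, function(v) mk(tape, v))

  # refresh the warm-started power-iteration state on the current raw
  # weights; sigma enters the tape as u' W v with u, v detached
  Weff <- list()
  pi_states <- list()
  for (nm in names(model$layers)) {
    ly <- model$layers[[nm]]
    st <- power_iteration(list(W = params[[paste0(nm, ".W")]],
                               u = ly$u, v = ly$v), n_iter = pi_iter)
    pi_states[[nm]] <- st
    Weff[[nm]] <- layer_effective_tape(tape, pn[[paste0(nm, ".W")]],
                                       pn[[paste0(nm, ".c")]], st$u, st$v)
  }
  theta <- t_silu(tape, t_add(tape, t_mm(tape, Weff$emb, data$Estar),
                              pn[["emb.b"]]), 0L)
  da <- t_sub(tape, t_cols(tape, theta, data$sys$ia),
              t_cols(tape, theta, data$sys$ib))
  ss <- t_colsums(tape, t_emul(tape, da, da))
  r_row <- t_exp(tape, t_emul(tape, ss, -model$beta_rbf))
  s_row <- t_add(tape, t_neg(tape, r_row), 1)
  ctx <- list(theta = theta, s_row = s_row, Weff = Weff, pn = pn,
              width = model$width)

  # rows are row indices into data$records; sub-frames kept their row names
  take <- function(df) df[rownames(df) %in% as.character(rows), , drop = FALSE]

  # stub models (prescribed q_fun) bypass the networks: their interaction
  # values enter the losses as constants
  s_num <- NULL
  if (!is.null(model$q_fun)) {
    th <- network_theta(model, data$Estar)
    Rn <- similarity_matrix(th, model$beta_rbf)
    s_num <- 1 - Rn[cbind(data$sys$ia, data$sys$ib)]
  }

  # interaction jets for a batch of records: projected fractions from the
  # half-difference form, then either the deep-set tape forward or the stub
  q_jets <- function(ia, ib, sysidx, x1, TK, Tstar, need_d2 = FALSE,
                     need_dT = FALSE) {
    if (is.null(model$q_fun)) {
      d <- t_emul(tape, t_cols(tape, s_row, sysidx), matrix(x1 - 0.5, 1L))
      tape_q_jets(tape, ctx, ia, ib, sysidx,
                  t_add(tape, d, 0.5),
                  t_add(tape, t_neg(tape, d), 0.5),
                  Tstar, need_d2 = need_d2, need_dT = need_dT)
    } else {
      s <- s_num[sysidx]
      qf <- model$q_fun(0.5 + s * (x1 - 0.5), TK)
      list(q = matrix(qf$q, 1L), qd1 = matrix(qf$qX, 1L),
           qd2 = if (need_d2) matrix(qf$qXX, 1L) else NULL,
           qTs = if (need_dT) matrix(qf$qT * model$scalers$t_std, 1L)
                 else NULL,
           s_rec = matrix(s, 1L))
    }
  }

  zero <- t_const(tape, 0)
  L <- list(TPXY = zero, TPX = zero, ACI = zero, LLE = zero, HE = zero,
            Gibbs = zero)
  n_lle_gap <- 0L

  tp <- take(data$tpxy)
  if (nrow(tp)) {
    jets <- q_jets(tp$ia, tp$ib, tp$sysidx, tp$x1, tp$T_K, tp$Tstar)
    lg <- tape_ln_gamma(tape, jets, tp$x1)
    err <- t_rbind(tape, list(lg$lng1, lg$lng2))
    sl <- t_smooth_l1(tape, err, rbind(tp$t_lng1, tp$t_lng2), SL1_BETA[["TPXY"]])
    L$TPXY <- t_emul(tape, t_sum(tape, sl), 0.5)
  }

  ac <- take(data$aci)
  if (nrow(ac)) {
    jets <- q_jets(ac$ia, ac$ib, ac$sysidx, ac$x1, ac$T_K, ac$Tstar)
    lg <- tape_ln_gamma(tape, jets, ac$x1)
    sel <- ifelse(ac$solute_idx == 1L, 1, 0)
    pred <- t_add(tape, t_emul(tape, lg$lng1, matrix(sel, 1L)),
                  t_emul(tape, lg$lng2, matrix(1 - sel, 1L)))
    sl <- t_smooth_l1(tape, pred, matrix(ac$ln_gamma_inf, 1L), SL1_BETA[["ACI"]])
    L$ACI <- t_emul(tape, t_sum(tape, sl), 0.5)
  }

  tx <- take(data$tpx)
  if (nrow(tx)) {
    jets <- q_jets(tx$ia, tx$ib, tx$sysidx, tx$x1, tx$T_K, tx$Tstar)
    lg <- tape_ln_gamma(tape, jets, tx$x1)
    p1 <- t_emul(tape, matrix(tx$ps1 * tx$x1, 1L), t_exp(tape, lg$lng1))
    p2 <- t_emul(tape, matrix(tx$ps2 * (1 - tx$x1), 1L), t_exp(tape, lg$lng2))
    sl <- t_smooth_l1(tape, t_log(tape, t_add(tape, p1, p2)),
                      matrix(tx$t_lnp, 1L), SL1_BETA[["TPX"]])
    L$TPX <- t_sum(tape, sl)
  }

  he <- take(data$he)
  if (nrow(he)) {
    jets <- q_jets(he$ia, he$ib, he$sysidx, he$x1, he$T_K, he$Tstar,
                   need_dT = TRUE)
    # hE in kJ/mol: -(R T^2 / s_T) x1 x2 dq/dT* / 1000
    fac <- -GAS_R * he$T_K^2 / model$scalers$t_std *
      he$x1 * (1 - he$x1) / 1000
    hpred <- t_emul(tape, matrix(fac, 1L), jets$qTs)
    sl <- t_smooth_l1(tape, hpred, matrix(he$hE_J_mol / 1000, 1L),
                      SL1_BETA[["HE"]])
    L$HE <- t_sum(tape, sl)
  }

  ll <- take(data$lle)
  if (nrow(ll)) {
    ng <- data$n_grid
    n <- nrow(ll)
    xg <- rep(data$xgrid, times = n)
    sysg <- rep(ll$sysidx, each = ng)
    iag <- rep(ll$ia, each = ng); ibg <- rep(ll$ib, each = ng)
    Tsg <- rep(ll$Tstar, each = ng)
    TKg <- rep(ll$T_K, each = ng)
    jets <- q_jets(iag, ibg, sysg, xg, TKg, Tsg, need_d2 = TRUE)
    x1r <- matrix(xg, 1L); x2r <- 1 - x1r
    g <- t_emul(tape, x1r * x2r, jets$q)
    curve_row <- t_add(tape, g, matrix(xlogx(xg) + xlogx(1 - xg), 1L))
    # second derivative of Dg_mix/RT on the grid
    d2g <- t_add(tape, t_add(tape,
             t_emul(tape, jets$q, -2),
             t_emul(tape, t_emul(tape, matrix(2 * (1 - 2 * xg), 1L),
                                 jets$s_rec), jets$qd1)),
             t_emul(tape, t_emul(tape, t_emul(tape, x1r * x2r, jets$s_rec),
                                 jets$s_rec), jets$qd2))
    interior <- as.numeric(data$xgrid > 0 & data$xgrid < 1)
    Srow <- t_add(tape, d2g, matrix(ifelse(rep(interior, n) > 0,
                                           1 / pmax(xg, 1e-12) +
                                           1 / pmax(1 - xg, 1e-12), Inf), 1L))
    Smat <- t_reshape(tape, Srow, ng, n)
    Smin <- t_colmin(tape, Smat)
    L$Gibbs <- t_sum(tape, t_relu(tape, Smin))
    mask <- as.numeric(node_val(Smin) < 0)
    n_lle_gap <- sum(mask)
    if (any(mask > 0)) {
      curves <- t_reshape(tape, curve_row, ng, n)
      sp <- surrogate_forward_tape(tape, surrogate, curves)
      has_p <- !is.na(ll$x1p); has_pp <- !is.na(ll$x1pp)
      wgt <- ifelse(has_p & has_pp, 0.5, 1)
      wp <- matrix(mask * wgt * has_p, 1L)
      wpp <- matrix(mask * wgt * has_pp, 1L)
      slp <- t_smooth_l1(tape, sp$x1_prime,
                         matrix(ifelse(has_p, ll$x1p, 0), 1L), SL1_BETA[["LLE"]])
      slpp <- t_smooth_l1(tape, sp$x1_doubleprime,
                          matrix(ifelse(has_pp, ll$x1pp, 0), 1L), SL1_BETA[["LLE"]])
      L$LLE <- t_add(tape, t_sum(tape, t_emul(tape, slp, wp)),
                     t_sum(tape, t_emul(tape, slpp, wpp)))
    }
  }

  if (weights$w_Lips > 0) {
    lp <- t_softplus(tape, pn[["emb.c"]])
    for (nm in c("mix1", "mix2", "prop1", "prop2"))
      lp <- t_emul(tape, lp, t_softplus(tape, pn[[paste0(nm, ".c")]]))
    L$Lips <- lp
    reg <- t_emul(tape, lp, weights$w_Lips)
  } else {
    # L2 fallback on the raw weight matrices
    l2 <- zero
    for (nm in names(params)) {
      if (!grepl("\\.W$", nm)) next
      l2 <- t_add(tape, l2, t_sum(tape, t_emul(tape, pn[[nm]], pn[[nm]])))
    }
    L$Lips <- l2
    reg <- t_emul(tape, l2, l2_lambda)
  }

  N_b <- length(rows)
  tot <- t_add(tape, t_add(tape, t_add(tape,
           t_add(tape, t_add(tape, L$TPXY, t_emul(tape, L$TPX, weights$w_TPX)),
                 L$ACI),
           t_emul(tape, L$LLE, weights$w_LLE)),
           t_emul(tape, L$HE, weights$w_HE)),
           t_add(tape, t_emul(tape, L$Gibbs, weights$w_Gibbs), reg))
  tot <- t_emul(tape, tot, 1 / N_b)

  list(tape = tape, pn = pn, total = tot,
       losses = lapply(L, node_val), N_b = N_b, n_lle_gap = n_lle_gap,
       pi_states = pi_states)
}

#' Evaluate the five data losses (no gradients)
#'
#' Runs the training forward pass on a set of records and returns the raw
#' (unweighted, un-normalized) data losses plus the Gibbs stability loss.
#'
#' @param model a `gibbsnn_network`
#' @param surrogate a trained `surrogate_network` (needed when LLE records
#'   are present)
#' @param records records data frame
#' @param components components frame with embeddings (and Antoine
#'   coefficients for VLE types)
#' @return named list `TPXY`, `TPX`, `ACI`, `LLE`, `HE`, `Gibbs`, `Lips`
#' @export
data_losses <- function(model, surrogate, records, components) {
  bad <- setdiff(unique(records$type), names(SL1_BETA))
  if (length(bad)) stop("unknown record type: ", paste(bad, collapse = ", "))
  data <- prepare_training_data(records, components, model$scalers)
  bl <- build_batch_losses(model, network_params(model), data,
                           seq_len(nrow(records)), surrogate,
                           default_loss_weights(), want_grad = FALSE,
                           pi_iter = 30L)
  bl$losses
}

#' Gibbs stability loss of a set of binary LLE records
#'
#' For each record, the minimum over the composition grid of the second
#' derivative of `Dg_mix/(RT)` enters as `max(0, min_d S)`: zero exactly
#' when the model predicts a miscibility gap at that state.
#'
#' @inheritParams data_losses
#' @param lle_records LLE records data frame
#' @return scalar loss
#' @export
gibbs_loss <- function(model, lle_records, components) {
  stopifnot(all(lle_records$type == "LLE"))
  tot <- 0
  for (k in seq_len(nrow(lle_records))) {
    ids <- strsplit(lle_records$component_ids[k], ";")[[1]]
    comp <- components[match(ids, components$component_id), , drop = FALSE]
    pv <- provider_network(model, comp)
    tot <- tot + max(0, stability_min(pv, lle_records$T_K[k])$S_min)
  }
  tot
}
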