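# Differentiable surrogate solver for binary liquid-liquid phase splits.
#
# A small fully connected network maps a discretized Dg_mix/(RT) curve (101
# nodes) onto the two coexisting phase compositions.  Permutation
# equivariance — reversing the curve must map (x', x'') to (1-x'', 1-x') —
# is enforced structurally: the network is evaluated on the curve and on its
# reversal, and the two results are cross-paired and averaged.  The solver
# is trained on convex-envelope labels of classical-model curves and is
# frozen during training of the main model (gradients flow only through its
# input curve).

#' Construct an (untrained) surrogate phase-split network
#'
#' Three fully connected layers of hidden size 64 (ReLU after the first
#' two); output of size 2 through a sigmoid.
#'
#' @param n_grid input curve length (101 in the reference pipeline)
#' @param hidden hidden layer width
#' @param seed seed for weight initialization
#' @return object of class `surrogate_network`
#' @export
surrogate_network <- function(n_grid = 101L, hidden = 64L, seed = 1L) {
  init <- function(o, i) {
    bound <- 1 / sqrt(i)
    list(W = matrix(stats::runif(o * i, -bound, bound), o, i),
         b = stats::runif(o, -bound, bound))
  }
  ls <- with_seed(seed, list(l1 = init(hidden, n_grid),
                             l2 = init(hidden, hidden),
                             l3 = init(2L, hidden)))
  structure(list(n_grid = as.integer(n_grid), hidden = as.integer(hidden),
                 layers = ls, version = CHECKPOINT_VERSION),
            class = "surrogate_network")
}

surrogate_raw <- function(sm, C) {
  h <- pmax(sm$layers$l1$W %*% C + sm$layers$l1$b, 0)
  h <- pmax(sm$layers$l2$W %*% h + sm$layers$l2$b, 0)
  stats::plogis(sm$layers$l3$W %*% h + sm$layers$l3$b)
}

#' Surrogate phase-split prediction
#'
#' @param sm a `surrogate_network`
#' @param curve numeric vector of length `n_grid`, or a matrix with one
#'   curve per column
#' @return list with `x1_prime` and `x1_doubleprime` (one value per curve).
#'   The cross-paired average of the forward and reversed passes guarantees
#'   `surrogate_forward(sm, rev(curve))` equals `(1 - x'', 1 - x')` exactly;
#'   the ordering `x' < x''` holds for trained models on double-well curves.
#' @export
surrogate_forward <- function(sm, curve) {
  C <- if (is.matrix(curve)) curve else matrix(curve, ncol = 1L)
  if (nrow(C) != sm$n_grid)
    stop(sprintf("curve length %d, expected %d", nrow(C), sm$n_grid))
  if (any(!is.finite(C))) stop("curve values must be finite")
  o  <- surrogate_raw(sm, C)
  or <- surrogate_raw(sm, C[nrow(C):1L, , drop = FALSE])
  list(x1_prime = as.numeric((o[1L, ] + 1 - or[2L, ]) / 2),
       x1_doubleprime = as.numeric((o[2L, ] + 1 - or[1L, ]) / 2))
}

# Tape version used inside the main training loop; surrogate weights are
# constants, gradients flow only into `curve_node` (n_grid x n).
surrogate_forward_tape <- function(tape, sm, curve_node) {
  pass <- function(Cn) {
    h <- t_relu(tape, t_add(tape, t_mm(tape, sm$layers$l1$W, Cn), sm$layers$l1$b))
    h <- t_relu(tape, t_add(tape, t_mm(tape, sm$layers$l2$W, h), sm$layers$l2$b))
    t_sigmoid(tape, t_add(tape, t_mm(tape, sm$layers$l3$W, h), sm$layers$l3$b))
  }
  o  <- pass(curve_node)
  or <- pass(t_rev_rows(tape, curve_node))
  xp  <- t_emul(tape, t_add(tape, t_sub(tape, t_row(tape, o, 1L),
                                        t_row(tape, or, 2L)), 1), 0.5)
  xpp <- t_emul(tape, t_add(tape, t_sub(tape, t_row(tape, o, 2L),
                                        t_row(tape, or, 1L)), 1), 0.5)
  list(x1_prime = xp, x1_doubleprime = xpp)
}

#' Convex-envelope labels for surrogate training
#'
#' For each requested state, builds the discretized `Dg_mix/(RT)` curve from
#' a ground-truth provider and labels it with the convex-envelope phase-split
#' endpoints.  States whose curve shows no miscibility gap are dropped.
#'
#' @param providers a single `gamma_provider`, or a named list keyed by
#'   `system_id`
#' @param lle_records data frame with column `T_K` (and `system_id` when
#'   `providers` is a list)
#' @param n_grid curve resolution
#' @return data frame with columns `T`, `curve_0` .. `curve_{n_grid-1}`,
#'   `x1_prime`, `x1_doubleprime` (labels ordered `x' < x''`); zero rows if
#'   every state was dropped
#' @export
make_surrogate_labels <- function(providers, lle_records, n_grid = 101L) {
  single <- inherits(providers, "gamma_provider")
  rows <- vector("list", nrow(lle_records))
  for (k in seq_len(nrow(lle_records))) {
    pv <- if (single) providers else providers[[lle_records$system_id[k]]]
    cv <- gmix_curve(pv, lle_records$T_K[k], n_grid)
    gaps <- cem_binary(cv)
    if (!nrow(gaps)) next
    # widest gap labels the curve
    gi <- which.max(gaps$x1_doubleprime - gaps$x1_prime)
    rows[[k]] <- c(lle_records$T_K[k], cv$values,
                   min(gaps$x1_prime[gi], gaps$x1_doubleprime[gi]),
                   max(gaps$x1_prime[gi], gaps$x1_doubleprime[gi]))
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- as.data.frame(do.call(rbind, rows))
  if (nrow(out))
    names(out) <- c("T", paste0("curve_", seq_len(n_grid) - 1L),
                    "x1_prime", "x1_doubleprime")
  out
}

#' Random classical-model training curves for the surrogate
#'
#' Draws demixing binary systems — symmetric two-suffix Margules with A
#' uniform in [2.05, 4], and asymmetric NRTL systems rejected until a gap is
#' present — and labels their 101-node curves with [cem_binary()].
#'
#' @param n number of labeled curves
#' @param seed integer seed
#' @param n_grid curve resolution
#' @param nrtl_frac fraction of NRTL (asymmetric) draws
#' @return labels data frame as in [make_surrogate_labels()]
#' @export
surrogate_training_curves <- function(n, seed = 1L, n_grid = 101L,
                                      nrtl_frac = 0.5) {
  out <- vector("list", n)
  with_seed(seed, {
    for (k in seq_len(n)) {
      repeat {
        if (stats::runif(1) >= nrtl_frac) {
          pv <- provider_margules(stats::runif(1, 2.05, 4))
        } else {
          tsum <- stats::runif(1, 2.4, 5)
          rho <- stats::runif(1, 0.7, 1.4)
          alpha <- stats::runif(1, 0.2, 0.4)
          pv <- provider_nrtl(tsum / (1 + rho), 0, tsum * rho / (1 + rho), 0,
                              alpha)
        }
        cv <- gmix_curve(pv, 300, n_grid)
        gaps <- cem_binary(cv)
        if (nrow(gaps)) break
      }
      gi <- which.max(gaps$x1_doubleprime - gaps$x1_prime)
      out[[k]] <- c(300, cv$values, gaps$x1_prime[gi], gaps$x1_doubleprime[gi])
    }
  })
  out <- as.data.frame(do.call(rbind, out))
  names(out) <- c("T", paste0("curve_", seq_len(n_grid) - 1L),
                  "x1_prime", "x1_doubleprime")
  out
}

label_matrices <- function(labels) {
  cc <- grep("^curve_", names(labels))
  list(curves = t(as.matrix(labels[, cc, drop = FALSE])),
       targets = t(as.matrix(labels[, c("x1_prime", "x1_doubleprime")])))
}

#' Train the surrogate phase-split solver
#'
#' Adam with a one-cycle learning-rate schedule and MSE loss; the epoch with
#' the lowest validation loss is returned.
#'
#' @param labels training labels (see [make_surrogate_labels()])
#' @param val_labels validation labels; when `NULL`, the last 10% of
#'   `labels` is held out (callers wanting system-wise hygiene pass an
#'   explicit split)
#' @param epochs training epochs
#' @param batch_size minibatch size
#' @param max_lr peak learning rate of the one-cycle schedule
#' @param seed seed for initialization and shuffling
#' @return a `surrogate_network` with attributes `history` (per-epoch
#'   train/validation loss), `best_epoch`, `val_mae` (validation mean
#'   absolute error of the phase compositions at the selected epoch)
#' @export
train_surrogate <- function(labels, val_labels = NULL, epochs = 200L,
                            batch_size = 256L, max_lr = 0.01, seed = 1L) {
  if (!nrow(labels)) stop("empty label set")
  if (is.null(val_labels)) {
    nv <- max(1L, floor(nrow(labels) * 0.1))
    val_labels <- labels[(nrow(labels) - nv + 1L):nrow(labels), , drop = FALSE]
    labels <- labels[seq_len(nrow(labels) - nv), , drop = FALSE]
  }
  tr <- label_matrices(labels); va <- label_matrices(val_labels)
  n_grid <- nrow(tr$curves)
  sm <- surrogate_network(n_grid = n_grid, seed = seed)
  params <- list(W1 = sm$layers$l1$W, b1 = sm$layers$l1$b,
                 W2 = sm$layers$l2$W, b2 = sm$layers$l2$b,
                 W3 = sm$layers$l3$W, b3 = sm$layers$l3$b)
  put <- function(sm, p) {
    sm$layers$l1$W <- p$W1; sm$layers$l1$b <- as.numeric(p$b1)
    sm$layers$l2$W <- p$W2; sm$layers$l2$b <- as.numeric(p$b2)
    sm$layers$l3$W <- p$W3; sm$layers$l3$b <- as.numeric(p$b3)
    sm
  }
  n <- ncol(tr$curves)
  steps_per_epoch <- ceiling(n / batch_size)
  total_steps <- steps_per_epoch * epochs
  opt <- adam_init(params)
  step <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  best <- list(loss = Inf, params = params, epoch = NA_integer_)
  with_seed(child_seed(seed, "surrogate-train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tl <- 0
      for (bi in seq_len(steps_per_epoch)) {
        idx <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, n)]
        step <- step + 1L
        lr <- one_cycle_lr(step, total_steps, max_lr)
        tape <- new_tape()
        pn <- lapply(params, function(v) t_param(tape, v))
        pred <- {
          pass <- function(Cn) {
            h <- t_relu(tape, t_add(tape, t_mm(tape, pn$W1, Cn), pn$b1))
            h <- t_relu(tape, t_add(tape, t_mm(tape, pn$W2, h), pn$b2))
            t_sigmoid(tape, t_add(tape, t_mm(tape, pn$W3, h), pn$b3))
          }
          Cb <- tr$curves[, idx, drop = FALSE]
          o  <- pass(t_const(tape, Cb))
          or <- pass(t_const(tape, Cb[n_grid:1L, , drop = FALSE]))
          t_emul(tape, t_add(tape, t_rbind(tape, list(
            t_sub(tape, t_row(tape, o, 1L), t_row(tape, or, 2L)),
            t_sub(tape, t_row(tape, o, 2L), t_row(tape, or, 1L)))), 1), 0.5)
        }
        d <- t_sub(tape, pred, tr$targets[, idx, drop = FALSE])
        loss <- t_emul(tape, t_sum(tape, t_emul(tape, d, d)),
                       1 / (2 * length(idx)))
        tape_backward(tape, loss)
        tl <- tl + loss$val * length(idx)
        params <- adam_step(params, lapply(pn, function(p) p$grad), opt, lr)
      }
      smc <- put(sm, params)
      pv <- surrogate_forward(smc, va$curves)
      vl <- mean((pv$x1_prime - va$targets[1L, ])^2 +
                 (pv$x1_doubleprime - va$targets[2L, ])^2) / 2
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = tl / n,
                                     val_loss = vl))
      if (vl < best$loss) best <- list(loss = vl, params = params, epoch = ep)
    }
  })
  sm <- put(sm, best$params)
  pv <- surrogate_forward(sm, va$curves)
  attr(sm, "history") <- hist
  attr(sm, "best_epoch") <- best$epoch
  attr(sm, "val_mae") <- mean(abs(c(pv$x1_prime - va$targets[1L, ],
                                    pv$x1_doubleprime - va$targets[2L, ])))
  sm
}
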