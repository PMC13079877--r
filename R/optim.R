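# Adam / AdamW and the one-cycle learning-rate schedule.

adam_init <- function(params) {
  e <- new.env(parent = emptyenv())
  e$m <- lapply(params, function(v) v * 0)
  e$v <- lapply(params, function(v) v * 0)
  e$t <- 0L
  e
}

# One optimizer step.  `weight_decay` is decoupled (AdamW) and applied only
# to parameters whose name is listed in `decay`; plain Adam when
# weight_decay = 0.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0, decay = character(0)) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && nm %in% decay)
      upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  params
}

# One-cycle schedule with cosine annealing: warm up from max_lr/div_factor
# to max_lr over pct_start of the run, then anneal to
# max_lr/(div_factor*final_div_factor).
one_cycle_lr <- function(step, total_steps, max_lr, pct_start = 0.3,
                         div_factor = 25, final_div_factor = 1e4) {
  lr0 <- max_lr / div_factor
  lr_end <- lr0 / final_div_factor
  up <- max(1, round(pct_start * total_steps))
  if (step <= up) {
    f <- (1 - cos(pi * step / up)) / 2
    lr0 + (max_lr - lr0) * f
  } else {
    f <- (1 - cos(pi * (step - up) / max(1, total_steps - up))) / 2
    max_lr + (lr_end - max_lr) * f
  }
}
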