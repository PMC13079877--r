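# Minimal reverse-mode automatic differentiation on matrices.
#
# A tape records every operation applied to tracked nodes; tape_backward()
# replays it in reverse, accumulating adjoints.  Nodes are environments so
# adjoints can be written in place.  Constants may be plain numerics: no node
# is created for them and no gradient flows into them.  This engine is what
# makes the model's activity coefficients "exact derivatives of the
# implemented forward pass": the composition/temperature derivatives are
# propagated analytically (see forward.R) and the resulting losses are
# differentiated with respect to the network parameters on this tape.

new_tape <- function(n = 2048L) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", n)
  tp$n <- 0L
  tp
}

is_node <- function(x) is.environment(x)

node_val <- function(x) if (is.environment(x)) x$val else x

tape_node <- function(tape, val, parents = NULL, bw = NULL, req = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$parents <- parents
  nd$bw <- bw
  nd$grad <- NULL
  if (is.null(req)) {
    req <- FALSE
    if (!is.null(parents)) {
      for (p in parents) if (is.environment(p) && p$req) { req <- TRUE; break }
    }
  }
  nd$req <- req
  i <- tape$n + 1L
  if (i > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[i]] <- nd
  tape$n <- i
  nd$id <- i
  nd
}

#' Create a parameter leaf on a tape
#'
#' @param tape a tape created by `new_tape()`
#' @param val numeric matrix or vector
#' @return a tape node that accumulates a gradient during [tape_backward()]
#' @keywords internal
t_param <- function(tape, val) tape_node(tape, val, req = TRUE)

t_const <- function(tape, val) tape_node(tape, val, req = FALSE)

#' Reverse sweep over a tape
#'
#' Seeds the output node with adjoint 1 and accumulates gradients into every
#' parameter leaf reachable from it.
#'
#' @param tape the tape
#' @param out scalar-valued output node
#' @keywords internal
tape_backward <- function(tape, out) {
  stopifnot(is.environment(out), length(out$val) == 1L)
  out$grad <- 1
  for (i in seq.int(out$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$bw)) next
    gs <- nd$bw(nd$grad, nd)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      if (is.environment(p) && p$req && !is.null(gs[[k]])) {
        p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
      }
    }
  }
  invisible(out)
}

## ---- elementary operations -------------------------------------------------

# Matrix product A %*% B.
t_mm <- function(tape, A, B) {
  av <- node_val(A); bv <- node_val(B)
  tape_node(tape, av %*% bv, list(A, B), function(g, nd) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

# A + B where B may be a same-shape matrix, a bias vector of length nrow(A)
# (recycled down columns, R's native recycling), or a scalar.
t_add <- function(tape, A, B) {
  av <- node_val(A); bv <- node_val(B)
  tape_node(tape, av + bv, list(A, B), function(g, nd) {
    ga <- g
    gb <- if (length(bv) == 1L) sum(g)
          else if (is.matrix(bv) && all(dim(bv) == dim(g))) g
          else if (!is.matrix(bv) && length(bv) == nrow(g)) rowSums(g)
          else stop("t_add: unsupported broadcast in backward")
    if (length(av) == 1L) ga <- sum(g)
    list(ga, gb)
  })
}

t_neg <- function(tape, A) {
  tape_node(tape, -node_val(A), list(A), function(g, nd) list(-g))
}

t_sub <- function(tape, A, B) t_add(tape, A, t_neg(tape, B))

# Elementwise product.  Supported shapes: equal; scalar with anything;
# row vector (1 x n) against m x n (column-wise broadcast).
t_emul <- function(tape, A, B) {
  av <- node_val(A); bv <- node_val(B)
  bcast <- function(v, like) {
    if (length(v) == 1L || identical(dim(v), dim(like))) v
    else matrix(v, nrow(like), ncol(like), byrow = TRUE)
  }
  val <- if (length(av) == 1L || length(bv) == 1L) av * bv
         else if (identical(dim(av), dim(bv))) av * bv
         else if (is.matrix(av) && is.matrix(bv) && nrow(bv) == 1L && ncol(bv) == ncol(av))
           av * bcast(bv, av)
         else if (is.matrix(av) && is.matrix(bv) && nrow(av) == 1L && ncol(av) == ncol(bv))
           bv * bcast(av, bv)
         else stop("t_emul: unsupported shapes")
  reduce_to <- function(g, v, other) {
    if (length(v) == 1L) sum(g * other)
    else if (identical(dim(v), dim(g))) g * other
    else matrix(colSums(g * other), 1L)  # v was a 1 x n row
  }
  tape_node(tape, val, list(A, B), function(g, nd) {
    oa <- if (length(bv) == 1L) bv else if (identical(dim(bv), dim(g))) bv else bcast(bv, g)
    ob <- if (length(av) == 1L) av else if (identical(dim(av), dim(g))) av else bcast(av, g)
    list(reduce_to(g, av, oa), reduce_to(g, bv, ob))
  })
}

t_ediv <- function(tape, A, B) {
  bv <- node_val(B)
  t_emul(tape, A, if (is_node(B)) t_pow(tape, B, -1) else 1 / bv)
}

t_pow <- function(tape, A, p) {
  av <- node_val(A)
  tape_node(tape, av^p, list(A), function(g, nd) list(g * p * av^(p - 1)))
}

t_exp <- function(tape, A) {
  val <- exp(node_val(A))
  tape_node(tape, val, list(A), function(g, nd) list(g * val))
}

t_log <- function(tape, A) {
  av <- node_val(A)
  tape_node(tape, log(av), list(A), function(g, nd) list(g / av))
}

t_relu <- function(tape, A) {
  av <- node_val(A)
  tape_node(tape, pmax(av, 0), list(A), function(g, nd) list(g * (av > 0)))
}

t_sigmoid <- function(tape, A) {
  val <- stats::plogis(node_val(A))
  tape_node(tape, val, list(A), function(g, nd) list(g * val * (1 - val)))
}

t_softplus <- function(tape, A) {
  av <- node_val(A)
  val <- softplus(av)
  tape_node(tape, val, list(A), function(g, nd) list(g * stats::plogis(av)))
}

# k-th derivative of the Sigmoid Linear Unit, as a tape primitive.  The
# backward pass of order k uses order k + 1, which is why silu_d goes one
# order beyond what the forward jets need.
t_silu <- function(tape, A, k = 0L) {
  av <- node_val(A)
  tape_node(tape, silu_d(av, k), list(A), function(g, nd) list(g * silu_d(av, k + 1L)))
}

t_sum <- function(tape, A) {
  av <- node_val(A)
  tape_node(tape, sum(av), list(A), function(g, nd) {
    list(array(g, dim = if (is.matrix(av)) dim(av) else length(av)))
  })
}

t_colsums <- function(tape, A) {
  av <- node_val(A)
  tape_node(tape, matrix(colSums(av), 1L), list(A), function(g, nd) {
    list(matrix(g, nrow(av), ncol(av), byrow = TRUE))
  })
}

# Stack rows: parts is a list of nodes/constants, each 1 x n or m x n.
t_rbind <- function(tape, parts) {
  vals <- lapply(parts, node_val)
  nr <- vapply(vals, NROW, 1L)
  val <- do.call(rbind, vals)
  ends <- cumsum(nr); starts <- ends - nr + 1L
  tape_node(tape, val, parts, function(g, nd) {
    lapply(seq_along(parts), function(k) g[starts[k]:ends[k], , drop = FALSE])
  })
}

# Column gather (duplicates allowed); backward scatter-adds.
t_cols <- function(tape, A, idx) {
  av <- node_val(A)
  idx <- as.integer(idx)
  tape_node(tape, av[, idx, drop = FALSE], list(A), function(g, nd) {
    gp <- matrix(0, nrow(av), ncol(av))
    acc <- rowsum(t(g), group = idx)          # sums per unique index, sorted
    gp[, as.integer(rownames(acc))] <- t(acc)
    list(gp)
  })
}

t_rev_rows <- function(tape, A) {
  av <- node_val(A)
  tape_node(tape, av[nrow(av):1L, , drop = FALSE], list(A), function(g, nd) {
    list(g[nrow(g):1L, , drop = FALSE])
  })
}

t_row <- function(tape, A, i) {
  av <- node_val(A)
  tape_node(tape, av[i, , drop = FALSE], list(A), function(g, nd) {
    gp <- matrix(0, nrow(av), ncol(av)); gp[i, ] <- g
    list(gp)
  })
}

t_reshape <- function(tape, A, nr, nc) {
  av <- node_val(A)
  tape_node(tape, matrix(av, nr, nc), list(A), function(g, nd) {
    list(matrix(g, nrow(av), ncol(av)))
  })
}

# Per-column minimum with subgradient routed to the (detached) argmin.
t_colmin <- function(tape, A) {
  av <- node_val(A)
  amin <- max.col(-t(av), ties.method = "first")
  tape_node(tape, matrix(av[cbind(amin, seq_len(ncol(av)))], 1L), list(A),
            function(g, nd) {
    gp <- matrix(0, nrow(av), ncol(av))
    gp[cbind(amin, seq_len(ncol(av)))] <- g
    list(gp)
  })
}

# Elementwise smooth-L1 (Huber-like) values; `target` is constant.
t_smooth_l1 <- function(tape, pred, target, beta) {
  pv <- node_val(pred)
  d <- pv - target
  val <- ifelse(abs(d) < beta, 0.5 * d^2 / beta, abs(d) - 0.5 * beta)
  tape_node(tape, val, list(pred), function(g, nd) {
    list(g * pmin(pmax(d / beta, -1), 1))
  })
}

## ---- scalar helpers --------------------------------------------------------

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-12))))

#' Derivatives of the Sigmoid Linear Unit
#'
#' `silu_d(x, k)` returns the k-th derivative of `x * sigmoid(x)` evaluated
#' elementwise, for k = 0..4.  Closed forms in terms of the logistic function
#' are used throughout the jet propagation of the forward pass.
#'
#' @param x numeric
#' @param k derivative order (0 to 4)
#' @return numeric of the same shape as `x`
#' @keywords internal
silu_d <- function(x, k = 0L) {
  s  <- stats::plogis(x)
  s1 <- s * (1 - s)
  if (k == 0L) return(x * s)
  if (k == 1L) return(s + x * s1)
  s2 <- s1 * (1 - 2 * s)
  if (k == 2L) return(2 * s1 + x * s2)
  s3 <- s2 * (1 - 2 * s) - 2 * s1^2
  if (k == 3L) return(3 * s2 + x * s3)
  s4 <- s3 * (1 - 2 * s) - 6 * s1 * s2
  if (k == 4L) return(4 * s3 + x * s4)
  stop("silu_d: k must be 0..4")
}
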