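# Phase equilibria from a gE provider: discretized Gibbs-energy-of-mixing
# curves, the spinodal stability criterion, convex-envelope liquid-liquid
# splits, an exact common-tangent solver, bubble pressures, and binodal
# temperature scans.

#' Discretized Gibbs energy of mixing curve
#'
#' `Dg_mix/(RT) = gE/RT + x1 ln x1 + x2 ln x2` on a uniform binary
#' composition grid, with the `x ln x -> 0` endpoint convention (endpoints
#' are exactly 0).
#'
#' @param provider a `gamma_provider` (binary)
#' @param T temperature in K
#' @param n_grid number of grid nodes (101 in the reference pipeline)
#' @return object of class `gmix_curve` with fields `T`, `x`, `values`
#' @export
gmix_curve <- function(provider, T, n_grid = 101L) {
  stopifnot(inherits(provider, "gamma_provider"), n_grid >= 5L)
  x <- seq(0, 1, length.out = n_grid)
  v <- provider$gE(x, T) + xlogx(x) + xlogx(1 - x)
  v[c(1L, n_grid)] <- 0
  if (any(!is.finite(v))) stop("gmix_curve: non-finite values")
  structure(list(T = T, x = x, values = v, provider = provider$name),
            class = "gmix_curve")
}

#' Minimum of the stability function
#'
#' `S(x) = d2(Dg_mix/RT)/dx^2 = d2(gE/RT)/dx^2 + 1/x1 + 1/x2`, evaluated by
#' exact differentiation of the provider on the interior grid nodes.  A
#' negative minimum is the necessary condition for a phase split.
#'
#' @inheritParams gmix_curve
#' @param grid composition grid (defaults to the 101-node grid)
#' @return list with `S_min` and `argmin` (the composition of the minimum)
#' @export
stability_min <- function(provider, T, grid = seq(0, 1, length.out = 101L)) {
  xi <- grid[grid > 0 & grid < 1]
  S <- provider$d2gE(xi, T) + 1 / xi + 1 / (1 - xi)
  k <- which.min(S)
  list(S_min = unname(S[k]), argmin = xi[k])
}

# Indices of the lower convex hull of (x, v), x strictly increasing
# (monotone chain).
lower_hull_idx <- function(x, v) {
  n <- length(x)
  h <- integer(n); m <- 0L
  for (i in seq_len(n)) {
    while (m >= 2L) {
      a <- h[m - 1L]; b <- h[m]
      # b above or on segment a-i  =>  drop b
      cross <- (x[b] - x[a]) * (v[i] - v[a]) - (v[b] - v[a]) * (x[i] - x[a])
      if (cross <= 0) m <- m - 1L else break
    }
    m <- m + 1L; h[m] <- i
  }
  h[seq_len(m)]
}

#' Convex-envelope phase splits of a binary curve
#'
#' Builds the lower convex hull of the discretized `Dg_mix/(RT)` curve; every
#' hull edge that skips at least two interior grid nodes is reported as a
#' miscibility gap with endpoints at the edge's vertices.  An empty result
#' means full miscibility.  A binary three-phase region appears as two gaps
#' sharing a vertex.
#'
#' @param curve a `gmix_curve`
#' @return data frame with columns `x1_prime`, `x1_doubleprime`, `gap_index`
#'   (ordered by composition); zero rows if no gap
#' @export
cem_binary <- function(curve) {
  stopifnot(inherits(curve, "gmix_curve"))
  h <- lower_hull_idx(curve$x, curve$values)
  span <- diff(h)
  gap <- which(span >= 3L)
  data.frame(x1_prime = curve$x[h[gap]],
             x1_doubleprime = curve$x[h[gap + 1L]],
             gap_index = seq_along(gap))
}

#' Exact binary phase split by common-tangent construction
#'
#' Independent of the convex envelope: brackets each miscibility gap on a
#' dense grid and polishes the two phase compositions with Newton iterations
#' on the isoactivity conditions `x' gamma' = x'' gamma''` for both
#' components, using the provider's exact derivatives.
#'
#' @inheritParams gmix_curve
#' @param n_dense dense bracketing grid size
#' @param tol convergence tolerance on the isoactivity residual
#' @return data frame like [cem_binary()]; zero rows if fully miscible
#' @export
lle_common_tangent <- function(provider, T, n_dense = 2001L, tol = 1e-12) {
  cv <- gmix_curve(provider, T, n_grid = n_dense)
  h <- lower_hull_idx(cv$x, cv$values)
  span <- diff(h)
  gaps <- which(span >= 3L)
  out <- data.frame(x1_prime = numeric(0), x1_doubleprime = numeric(0),
                    gap_index = integer(0))
  lngam <- function(x) provider$ln_gamma(x, T)
  for (gi in seq_along(gaps)) {
    xa <- cv$x[h[gaps[gi]]]; xb <- cv$x[h[gaps[gi] + 1L]]
    xa <- max(xa, 1e-10); xb <- min(xb, 1 - 1e-10)
    for (it in 1:100) {
      la <- lngam(xa); lb <- lngam(xb)
      F1 <- log(xa) + la$lng1 - log(xb) - lb$lng1
      F2 <- log(1 - xa) + la$lng2 - log(1 - xb) - lb$lng2
      if (max(abs(c(F1, F2))) < tol) break
      d2a <- provider$d2gE(xa, T); d2b <- provider$d2gE(xb, T)
      J11 <- 1 / xa + (1 - xa) * d2a
      J12 <- -(1 / xb + (1 - xb) * d2b)
      J21 <- -1 / (1 - xa) - xa * d2a
      J22 <- 1 / (1 - xb) + xb * d2b
      det <- J11 * J22 - J12 * J21
      if (!is.finite(det) || abs(det) < 1e-300) break
      dxa <- (F1 * J22 - F2 * J12) / det
      dxb <- (J11 * F2 - J21 * F1) / det
      step <- 1
      # keep iterates inside (0,1) and ordered
      while (step > 1e-4) {
        na <- xa - step * dxa; nb <- xb - step * dxb
        if (na > 1e-12 && nb < 1 - 1e-12 && na < nb) break
        step <- step / 2
      }
      xa <- xa - step * dxa; xb <- xb - step * dxb
    }
    out <- rbind(out, data.frame(x1_prime = xa, x1_doubleprime = xb,
                                 gap_index = gi))
  }
  out
}

#' Bubble pressure of a binary mixture
#'
#' Extended Raoult's law with an ideal vapor phase:
#' `p = sum_i p_i^s x_i gamma_i`, `y_i = p_i^s x_i gamma_i / p`.
#'
#' @inheritParams gmix_curve
#' @param x1 liquid mole fraction of component 1
#' @param antoine 2 x 3 matrix of Antoine coefficients (rows = components);
#'   an optional attribute `T_range` (2 x 2, per-component validity bounds in
#'   K) triggers a warning, not an error, outside the range
#' @return list with `p` (bar) and `y` (vapor mole fractions)
#' @export
bubble_pressure <- function(provider, x1, T, antoine) {
  stopifnot(length(x1) == 1L, x1 >= 0, x1 <= 1)
  tr <- attr(antoine, "T_range")
  if (!is.null(tr) && (any(T < tr[, 1L]) || any(T > tr[, 2L])))
    warning(sprintf("T = %.2f K outside Antoine validity range", T))
  ps <- antoine_psat(antoine, T)
  lg <- provider$ln_gamma(x1, T)
  pp <- ps * c(x1, 1 - x1) * exp(c(lg$lng1, lg$lng2))
  p <- sum(pp)
  list(p = p, y = pp / p)
}

#' Binodal temperature scan
#'
#' Runs [cem_binary()] on a grid of temperatures and collects all detected
#' miscibility gaps; a gap that exists at one temperature and not at the next
#' brackets a critical solution temperature, reported as the midpoint of the
#' bracketing pair.
#'
#' @inheritParams gmix_curve
#' @param T_range numeric length-2, scan bounds in K
#' @param step temperature step in K
#' @return list with `binodal` (data frame `T, x1_prime, x1_doubleprime,
#'   gap_index`) and `critical_T` (data frame `T, direction` where direction
#'   is `"closing"` when the gap disappears with rising T and `"opening"`
#'   otherwise)
#' @export
lle_temperature_scan <- function(provider, T_range, step, n_grid = 101L) {
  stopifnot(length(T_range) == 2L, all(is.finite(T_range)), step > 0)
  Ts <- seq(T_range[1L], T_range[2L], by = step)
  rows <- vector("list", length(Ts))
  ngap <- integer(length(Ts))
  for (k in seq_along(Ts)) {
    g <- cem_binary(gmix_curve(provider, Ts[k], n_grid))
    ngap[k] <- nrow(g)
    if (nrow(g)) rows[[k]] <- cbind(T = Ts[k], g)
  }
  binodal <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(binodal))
    binodal <- data.frame(T = numeric(0), x1_prime = numeric(0),
                          x1_doubleprime = numeric(0), gap_index = integer(0))
  chg <- which(diff(ngap > 0L) != 0L)
  critical_T <- data.frame(
    T = Ts[chg] + step / 2,
    direction = ifelse(diff(ngap > 0L)[chg] < 0L, "closing", "opening"))
  list(binodal = binodal, critical_T = critical_T)
}
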