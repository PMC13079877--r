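# Gibbs-energy-of-mixing curves, stability, convex-envelope splits, the
# common-tangent oracle, bubble pressures and binodal scans.

test_that("gmix curve matches hand-evaluated values", {
  cv <- gmix_curve(provider_ideal(), 300)
  expect_length(cv$values, 101L)
  expect_identical(cv$values[c(1, 101)], c(0, 0))
  expect_equal(cv$values[51], log(0.5), tolerance = 1e-12)
  cvm <- gmix_curve(provider_margules(2.5), 300)
  expect_equal(cvm$values[51], 0.25 * 2.5 + log(0.5), tolerance = 1e-12)
  expect_equal(gmix_curve(provider_margules(2.5), 300, n_grid = 51)$x,
               seq(0, 1, by = 0.02))
})

test_that("stability minimum matches closed forms", {
  s <- stability_min(provider_ideal(), 300)
  expect_equal(s$S_min, 4)
  expect_equal(s$argmin, 0.5)
  expect_equal(stability_min(provider_margules(2), 300)$S_min, 0,
               tolerance = 1e-12)
  expect_equal(stability_min(provider_margules(2.5), 300)$S_min, -1)
})

test_that("convex envelope finds no gap in convex curves", {
  expect_identical(nrow(cem_binary(gmix_curve(provider_ideal(), 300))), 0L)
  expect_identical(nrow(cem_binary(gmix_curve(provider_margules(1.5), 300))), 0L)
  # marginal case A = 2: inflection exactly at zero curvature, no gap
  expect_identical(nrow(cem_binary(gmix_curve(provider_margules(2), 300))), 0L)
})

test_that("convex envelope endpoints agree with the bisection oracle", {
  g <- cem_binary(gmix_curve(provider_margules(2.5), 300))
  expect_identical(nrow(g), 1L)
  oracle <- margules_gap_bisection(2.5)
  expect_equal(oracle[1], 0.1448, tolerance = 1e-3)
  expect_lt(abs(g$x1_prime - oracle[1]), 0.0100001)
  expect_lt(abs(g$x1_doubleprime - oracle[2]), 0.0100001)
})

test_that("crafted double-double-well curve yields two ordered gaps", {
  x <- seq(0, 1, length.out = 101)
  # a W-shaped curve: ideal mixing plus a composition-dependent interaction
  # with a stabilizing ridge at equimolar composition
  v <- gibbsnn:::xlogx(x) + gibbsnn:::xlogx(1 - x) +
    x * (1 - x) * (12 * (x - 0.5)^2 + 1)
  v[c(1, 101)] <- 0
  cv <- structure(list(T = 300, x = x, values = v, provider = "fixture"),
                  class = "gmix_curve")
  g <- cem_binary(cv)
  expect_identical(nrow(g), 2L)
  expect_true(all(g$x1_prime < g$x1_doubleprime))
  expect_lt(g$x1_doubleprime[1], g$x1_prime[2])
  expect_identical(g$gap_index, 1:2)
})

test_that("hull values never exceed the curve and touch at vertices", {
  set.seed(5)
  for (rep in 1:5) {
    A <- runif(1, 2.2, 3.5)
    cv <- gmix_curve(provider_margules(A), 300)
    h <- gibbsnn:::lower_hull_idx(cv$x, cv$values)
    env <- approx(cv$x[h], cv$values[h], xout = cv$x)$y
    expect_true(all(env <= cv$values + 1e-12))
    expect_equal(env[h], cv$values[h])
  }
})

test_that("envelope and common-tangent oracle agree on random draws", {
  set.seed(77)
  for (rep in 1:25) {
    pv <- if (rep %% 2 == 0) provider_margules(runif(1, 2.05, 4))
          else {
            tsum <- runif(1, 2.6, 5); rho <- runif(1, 0.75, 1.3)
            provider_nrtl(tsum / (1 + rho), 0, tsum * rho / (1 + rho), 0,
                          runif(1, 0.2, 0.4))
          }
    ct <- lle_common_tangent(pv, 310)
    g <- cem_binary(gmix_curve(pv, 310))
    if (nrow(ct) == 0L) { expect_identical(nrow(g), 0L); next }
    expect_identical(nrow(g), nrow(ct))
    expect_lt(max(abs(g$x1_prime - ct$x1_prime)), 0.0100001)
    expect_lt(max(abs(g$x1_doubleprime - ct$x1_doubleprime)), 0.0100001)
    # oracle satisfies isoactivity in both components
    lg1 <- pv$ln_gamma(ct$x1_prime, 310); lg2 <- pv$ln_gamma(ct$x1_doubleprime, 310)
    expect_lt(abs(ct$x1_prime * exp(lg1$lng1) -
                  ct$x1_doubleprime * exp(lg2$lng1)), 1e-8)
    expect_lt(abs((1 - ct$x1_prime) * exp(lg1$lng2) -
                  (1 - ct$x1_doubleprime) * exp(lg2$lng2)), 1e-8)
  }
})

test_that("no false gaps on miscible draws and spinodal iff envelope gap", {
  set.seed(78)
  for (rep in 1:25) {
    A <- runif(1, -1, 1.95)
    pv <- provider_margules(A)
    expect_identical(nrow(cem_binary(gmix_curve(pv, 300))), 0L)
    expect_gte(stability_min(pv, 300)$S_min, 0)
  }
  for (rep in 1:10) {
    A <- runif(1, 2.05, 4)
    pv <- provider_margules(A)
    expect_gt(nrow(cem_binary(gmix_curve(pv, 300))), 0L)
    expect_lt(stability_min(pv, 300)$S_min, 0)
  }
})

test_that("bubble pressure follows extended Raoult's law", {
  # Antoine coefficients giving p_s = 1.2 and 0.6 bar at any T
  ant <- rbind(c(log10(1.2), 0, 0), c(log10(0.6), 0, 0))
  bp <- bubble_pressure(provider_ideal(), 0.5, 350, ant)
  expect_equal(bp$p, 0.9, tolerance = 1e-12)
  expect_equal(bp$y[1], 2 / 3, tolerance = 1e-12)
  expect_equal(sum(bp$y), 1, tolerance = 1e-12)
  expect_equal(bubble_pressure(provider_ideal(), 1, 350, ant)$p, 1.2)
  # gamma from a TPXY record round-trips through Eq-4 algebra
  pv <- provider_margules(1.7)
  bp2 <- bubble_pressure(pv, 0.3, 350, ant)
  ps <- antoine_psat(ant, 350)
  gam <- bp2$p * bp2$y / (ps * c(0.3, 0.7))
  lg <- pv$ln_gamma(0.3, 350)
  expect_equal(log(gam), c(lg$lng1, lg$lng2), tolerance = 1e-10)
  bp3 <- bubble_pressure(pv, 0.3, 350, ant)
  expect_equal(sum(bp3$y), 1, tolerance = 1e-12)
  # validity range triggers a warning, not an error
  antr <- ant; attr(antr, "T_range") <- rbind(c(300, 320), c(300, 320))
  expect_warning(bubble_pressure(pv, 0.3, 350, antr), "Antoine")
})

test_that("temperature scan brackets the critical solution temperature", {
  # A(T) = 500/T: gap exists iff A > 2, i.e. T < 250 K
  pv <- provider_margules(0, 500)
  scan <- lle_temperature_scan(pv, c(230, 270), step = 2)
  expect_gt(nrow(scan$binodal), 0)
  expect_true(all(scan$binodal$T < 250))
  expect_identical(nrow(scan$critical_T), 1L)
  expect_lte(abs(scan$critical_T$T - 250), 1.0000001)  # within step/2
  expect_identical(scan$critical_T$direction, "closing")
  # constant A below the critical value: empty binodal
  scan2 <- lle_temperature_scan(provider_margules(1.5), c(280, 300), step = 5)
  expect_identical(nrow(scan2$binodal), 0L)
  # constant A = 2.5: binodal width independent of temperature
  scan3 <- lle_temperature_scan(provider_margules(2.5), c(280, 320), step = 10)
  expect_equal(length(unique(scan3$binodal$x1_prime)), 1L)
})
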