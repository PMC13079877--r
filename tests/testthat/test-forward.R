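# The forward pass: similarity, lumping, projection, interaction symmetry,
# excess Gibbs energy, activity coefficients and excess enthalpy.

test_that("similarity is 1 on the diagonal and follows the RBF", {
  theta <- matrix(c(0, 0.1, 3), 1L)   # 1-d refined embeddings
  R <- gibbsnn:::similarity_matrix(theta, 100)
  expect_identical(diag(R), c(1, 1, 1))
  expect_equal(R[1, 2], exp(-1))          # beta * 0.01 = 1
  expect_equal(R[2, 1], R[1, 2])
  expect_equal(R[1, 3], 0)                # far limit underflows to 0
  theta2 <- matrix(c(0.7, 0.7), 1L)
  expect_identical(gibbsnn:::similarity_matrix(theta2, 100)[1, 2], 1)
})

test_that("lumping merges identical components", {
  x <- c(0.2, 0.3, 0.5)
  expect_equal(lump_mole_fractions(x, diag(3)), x)
  R <- diag(3); R[2, 3] <- R[3, 2] <- 1   # B and C identical, A dissimilar
  expect_equal(lump_mole_fractions(x, R), c(0.2, 0.8, 0.8))
  expect_equal(lump_mole_fractions(x, matrix(1, 3, 3)), c(1, 1, 1))
})

test_that("Muggianu projection matches hand-derived values", {
  xt <- c(0.2, 0.3, 0.5)
  expect_equal(muggianu_project(xt, 1, 2), c(0.45, 0.55))
  expect_equal(muggianu_project(xt, 1, 3), c(0.35, 0.65))
  expect_equal(muggianu_project(xt, 2, 3), c(0.40, 0.60))
  expect_identical(sum(muggianu_project(xt, 1, 3)), 1)  # exact summation
  expect_equal(muggianu_project(c(0.4, 0.4), 1, 2), c(0.5, 0.5))
  # binary case returns the lumped fractions unchanged
  xb <- c(0.31, 0.69)
  expect_equal(muggianu_project(xb, 1, 2), xb, tolerance = 1e-15)
  expect_error(muggianu_project(xt, 2, 2))
})

test_that("binary interaction is symmetric and vanishes for identical pairs", {
  m <- tiny_network(seed = 11)
  E <- random_embeddings(2, seed = 5)
  rs <- refine_and_similarity(m, E)
  jets <- gibbsnn:::pair_interaction_jets(m, gibbsnn:::network_weff(m),
                                          rs$theta[, c(1, 2)],
                                          rs$theta[, c(2, 1)],
                                          c(0.3, 0.7), 0.1,
                                          Xj = c(0.7, 0.3))
  # swapping (theta_i, Xi) <-> (theta_j, Xj) leaves phi unchanged bitwise
  expect_identical(jets$phi[1], jets$phi[2])
  # identical components: q = 0 exactly via the (1 - R) factor
  Eid <- E[, c(1, 1)]
  ev <- gibbsnn:::gibbsnn_eval(m, Eid, c(0.4, 0.6), 320)
  expect_identical(ev$subsystems$q_ij, 0)
  expect_identical(ev$gE_RT, 0)
  # dimension mismatch is caught
  expect_error(refine_and_similarity(m, random_embeddings(2, D = 5)),
               "dimension")
})

test_that("excess Gibbs energy follows the pairwise assembly", {
  stub <- gibbsnn_stub(constant_q(2), D = 8)
  E <- random_embeddings(3, seed = 2)
  expect_equal(excess_gibbs(stub, E, c(1, 0, 0), 300), 0)
  expect_equal(excess_gibbs(stub, E, rep(1 / 3, 3), 300), 2 / 3)
})

test_that("constant-q stub reproduces two-suffix Margules closed forms", {
  A <- 2
  stub <- gibbsnn_stub(constant_q(A), D = 8)
  E <- random_embeddings(2, seed = 3)
  x1 <- seq(0, 1, length.out = 101)
  ev <- gibbsnn:::gibbsnn_binary_eval(stub, E, x1, 310)
  expect_equal(ev$ln_gamma1, A * (1 - x1)^2, tolerance = 1e-10)
  expect_equal(ev$ln_gamma2, A * x1^2, tolerance = 1e-10)
  expect_equal(ev$ln_gamma1[51], 0.5)   # x1 = 0.5 -> A x2^2 = 0.5
  expect_equal(ev$ln_gamma1[1], 2)      # infinite dilution -> A
})

test_that("excess enthalpy follows the Gibbs-Helmholtz chain rule", {
  E <- random_embeddings(2, seed = 4)
  # temperature-independent interaction -> hE = 0
  stub0 <- gibbsnn_stub(constant_q(1.3), D = 8)
  expect_equal(excess_enthalpy(stub0, E, c(0.4, 0.6), 350), 0)
  # q(T) = A0 + A1/T -> hE = R A1 x1 x2, independent of A0
  stub <- gibbsnn_stub(temperature_q(0.7, 100), D = 8)
  expect_equal(excess_enthalpy(stub, E, c(0.5, 0.5), 300), 207.86,
               tolerance = 1e-4)
  expect_equal(excess_enthalpy(stub, E, c(0.5, 0.5), 400),
               8.31446 * 100 * 0.25, tolerance = 1e-10)
  # real network: exact derivative against central finite difference in T
  m <- tiny_network(seed = 12)
  x <- c(0.35, 0.65); T0 <- 320; h <- 0.01
  g <- function(T) gibbsnn:::gibbsnn_eval(m, E, x, T, need_hE = FALSE)$gE_RT
  hE_fd <- -8.31446 * T0^2 * (g(T0 + h) - g(T0 - h)) / (2 * h)
  expect_equal(excess_enthalpy(m, E, x, T0), hE_fd, tolerance = 1e-4 * abs(hE_fd))
})

test_that("pure-component limits and boundary states are exact", {
  m <- tiny_network(seed = 13)
  E <- random_embeddings(3, seed = 6)
  ev <- gibbsnn:::gibbsnn_eval(m, E[, 1:2], c(1, 0), 300)
  expect_lt(abs(ev$ln_gamma[1]), 1e-12)
  expect_identical(ev$gE_RT, 0)
  ev3 <- gibbsnn:::gibbsnn_eval(m, E, c(0, 0.4, 0.6), 300)
  expect_true(all(is.finite(ev3$ln_gamma)))
})

test_that("activity coefficients are permutation-equivariant", {
  m <- tiny_network(seed = 14)
  set.seed(99)
  for (N in 2:4) {
    E <- random_embeddings(N, seed = N + 20)
    x <- random_simplex(N)
    ev <- gibbsnn:::gibbsnn_eval(m, E, x, 340)
    for (rep in 1:3) {
      p <- sample(N)
      evp <- gibbsnn:::gibbsnn_eval(m, E[, p], x[p], 340)
      expect_lt(max(abs(evp$ln_gamma - ev$ln_gamma[p])), 1e-10)
      expect_lt(abs(evp$gE_RT - ev$gE_RT), 1e-10)
    }
  }
})

test_that("duplicating a component reduces to the pseudo-binary mixture", {
  m <- tiny_network(seed = 15)
  E <- random_embeddings(2, seed = 9)
  ev2 <- gibbsnn:::gibbsnn_eval(m, E, c(0.2, 0.8), 310)
  set.seed(1)
  for (rep in 1:5) {
    a <- runif(1, 0, 0.8)
    E3 <- E[, c(1, 2, 2)]
    ev3 <- gibbsnn:::gibbsnn_eval(m, E3, c(0.2, a, 0.8 - a), 310)
    expect_lt(abs(ev3$gE_RT - ev2$gE_RT), 1e-8)
    expect_lt(abs(ev3$ln_gamma[1] - ev2$ln_gamma[1]), 1e-8)
  }
})

test_that("Gibbs-Duhem holds along random in-simplex directions", {
  set.seed(2024)
  eps <- 1e-5
  worst <- 0
  for (draw in 1:40) {
    N <- sample(2:5, 1)
    m <- tiny_network(seed = draw, D = 6, width = 8)
    E <- random_embeddings(N, D = 6, seed = 1000 + draw)
    x <- 0.9 * random_simplex(N) + 0.1 / N   # keep x + eps*d on the simplex
    d <- simplex_direction(N)
    l0 <- gibbsnn:::gibbsnn_eval(m, E, x, 330)$ln_gamma
    l1 <- gibbsnn:::gibbsnn_eval(m, E, x + eps * d, 330)$ln_gamma
    worst <- max(worst, abs(sum(x * (l1 - l0))) / eps)
  }
  expect_lt(worst, 1e-3)
})

test_that("infinite-dilution evaluation returns the solute limit", {
  stub <- gibbsnn_stub(constant_q(2), D = 8)
  E <- random_embeddings(2, seed = 10)
  expect_equal(ln_gamma_infinite_dilution(stub, E, 1, 1, 300), 2,
               tolerance = 1e-12)
  # solute identical to the solvent: pseudo-pure, ln gamma = 0
  m <- tiny_network(seed = 16)
  Eid <- E[, c(1, 1)]
  expect_lt(abs(ln_gamma_infinite_dilution(m, Eid, 1, 1, 300)), 1e-12)
  # ternary solvent symmetry with a symmetric stub
  E3 <- random_embeddings(3, seed = 11)
  v1 <- ln_gamma_infinite_dilution(stub, E3, 1, c(0.5, 0.5), 320)
  v2 <- ln_gamma_infinite_dilution(stub, E3[, c(1, 3, 2)], 1, c(0.5, 0.5), 320)
  expect_equal(v1, v2, tolerance = 1e-12)
  expect_error(ln_gamma_infinite_dilution(stub, E, 5, 1, 300), "out of range")
})

test_that("the tape forward agrees with the numeric forward", {
  ds <- gibbsnn:::synthetic_dataset(
    5, seed = 21, miscibility_mix = 0.6,
    counts = list(tpxy = 3, tpx = 2, aci = 2, lle = 2, he = 2))
  sc <- fit_scalers(ds$records, ds$components)
  m <- gibbsnn_network(D = 16, width = 8, scalers = sc, seed = 30)
  sm <- surrogate_network(seed = 2)
  losses <- data_losses(m, sm, ds$records, ds$components)
  # recompute TPXY loss through the independent numeric path
  mf <- freeze_network(m)
  E <- gibbsnn:::embedding_matrix(ds$components)
  tp <- ds$records[ds$records$type == "TPXY", ]
  lt <- 0
  for (k in seq_len(nrow(tp))) {
    ids <- strsplit(tp$component_ids[k], ";")[[1]]
    ev <- gibbsnn:::gibbsnn_binary_eval(mf, E[, ids], tp$x1[k], tp$T_K[k])
    ant <- as.matrix(ds$components[match(ids, ds$components$component_id),
                                   c("antoine_a", "antoine_b", "antoine_c")])
    ps <- antoine_psat(ant, tp$T_K[k])
    tg <- log(c(tp$p_bar[k] * tp$y1[k] / (ps[1] * tp$x1[k]),
                tp$p_bar[k] * tp$y2[k] / (ps[2] * tp$x2[k])))
    lt <- lt + mean(smooth_l1(c(ev$ln_gamma1, ev$ln_gamma2), tg, 1))
  }
  expect_equal(losses$TPXY, lt, tolerance = 1e-8)
})
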