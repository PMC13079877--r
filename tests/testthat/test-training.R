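# Lipschitz machinery, loss terms, splitting, and the optimization loop.

test_that("spectral norm estimate matches known singular values", {
  expect_equal(spectral_norm_estimate(diag(4))$sigma, 1)
  set.seed(1)
  st <- NULL; sig <- 0
  for (i in 1:10) {
    st <- spectral_norm_estimate(diag(c(3, 1)), n_iter = 1, state = st)
    expect_gte(st$sigma, sig - 1e-12)  # non-decreasing across iterations
    sig <- st$sigma
  }
  expect_equal(st$sigma, 3, tolerance = 1e-6)
  # random matrix against the SVD oracle
  W <- matrix(rnorm(30), 5, 6)
  expect_equal(spectral_norm_estimate(W, n_iter = 50)$sigma,
               max(svd(W)$d), tolerance = 1e-9)
  expect_lte(spectral_norm_estimate(W, n_iter = 2)$sigma,
             max(svd(W)$d) + 1e-12)  # Rayleigh estimate from below
  expect_equal(spectral_norm_estimate(matrix(0, 3, 3))$sigma, 1e-12)
})

test_that("scaled layers have spectral norm softplus(c*)", {
  set.seed(2)
  for (rep in 1:5) {
    ly <- gibbsnn:::new_lipschitz_layer(8L, 10L)
    ly$c_star <- rnorm(1)
    Weff <- gibbsnn:::layer_effective(ly, n_iter = 10L)
    expect_equal(max(svd(Weff)$d), gibbsnn:::softplus(ly$c_star),
                 tolerance = 1e-3)
  }
})

test_that("the Lipschitz product bounds network differences empirically", {
  m <- tiny_network(seed = 31, D = 8, width = 16)
  L <- lipschitz_loss(m)
  Weff <- gibbsnn:::network_weff(m)
  f <- function(e) {
    th <- silu_d(Weff$emb %*% e + m$layers$emb$b, 0)
    c1 <- rbind(th, 0.3, 0.1)
    a <- silu_d(Weff$mix1 %*% c1 + m$layers$mix1$b, 0)
    a <- silu_d(Weff$mix2 %*% a + m$layers$mix2$b, 0)
    a <- silu_d(Weff$prop1 %*% a + m$layers$prop1$b, 0)
    Weff$prop2 %*% a + m$layers$prop2$b
  }
  set.seed(3)
  bound <- L * 1.1^4   # four hidden activations on the path
  for (i in 1:1000) {
    e0 <- matrix(rnorm(8), ncol = 1)
    e1 <- e0 + matrix(rnorm(8, sd = 0.3), ncol = 1)
    expect_lte(sqrt(sum((f(e1) - f(e0))^2)),
               bound * sqrt(sum((e1 - e0)^2)) + 1e-12)
  }
})

test_that("smooth-L1 matches its closed form", {
  expect_identical(smooth_l1(1, 1, 1), 0)
  expect_equal(smooth_l1(0.5, 0, 1), 0.125)
  expect_equal(smooth_l1(2, 0, 1), 1.5)
  expect_equal(smooth_l1(0.35, 0, 0.35), 0.175)  # value at the knee
  expect_equal(smooth_l1(0, 0.35, 0.35), 0.175)  # symmetric in the sign
})

test_that("Lipschitz loss is the product of layer constants", {
  m <- gibbsnn_network(D = 4, width = 4, seed = 1)
  for (nm in names(m$layers))
    m$layers[[nm]]$c_star <- gibbsnn:::softplus_inv(2)
  expect_equal(lipschitz_loss(m), 32, tolerance = 1e-12)
  # strictly decreasing in any single c*
  m$layers$mix1$c_star <- gibbsnn:::softplus_inv(1.5)
  expect_lt(lipschitz_loss(m), 32)
})

test_that("total loss weights and batch normalization are faithful", {
  L0 <- list(TPXY = 0, TPX = 0, ACI = 0, LLE = 0, HE = 0, Gibbs = 0, Lips = 1)
  w <- list(w_TPX = 1, w_LLE = 5, w_HE = 0.1, w_Gibbs = 0.1, w_Lips = 0.1)
  expect_equal(total_loss(L0, w, 10), 0.01)
  L1 <- list(TPXY = 1, TPX = 1, ACI = 1, LLE = 1, HE = 1, Gibbs = 1, Lips = 1)
  w1 <- list(w_TPX = 1, w_LLE = 1, w_HE = 1, w_Gibbs = 1, w_Lips = 1)
  expect_equal(total_loss(L1, w1, 1), 7)
  expect_equal(total_loss(L1, w1, 2), 3.5)  # doubling N_b halves the loss
  expect_error(total_loss(L1, list(w_TPX = -1, w_LLE = 1, w_HE = 1,
                                   w_Gibbs = 1, w_Lips = 1), 1),
               "nonnegative")
})

test_that("data losses match hand-computed smooth-L1 sums", {
  # stub with constant interaction A = 2; flat Antoine -> p_s = 1 bar
  E <- random_embeddings(2, seed = 41)
  comps <- pair_components(E)
  stub <- gibbsnn_stub(constant_q(2), D = 8)
  sm <- surrogate_network(seed = 1)
  # model predicts ln gamma = (A x2^2, A x1^2) = (0.5, 0.5) at x1 = 0.5;
  # craft the record so the errors are exactly (0.5, 0)
  t1 <- 0.5 + 0.5; t2 <- 0.5
  pp <- c(0.5 * exp(t1), 0.5 * exp(t2))
  rec <- make_record("TPXY", T_K = 300, p_bar = sum(pp), x1 = 0.5, x2 = 0.5,
                     y1 = pp[1] / sum(pp), y2 = pp[2] / sum(pp))
  l <- data_losses(stub, sm, rec, comps)
  expect_equal(l$TPXY, (0.125 + 0) / 2, tolerance = 1e-10)
  expect_equal(l$TPX, 0)
  # perfect predictions give zero losses
  pp0 <- c(0.5 * exp(0.5), 0.5 * exp(0.5))
  rec0 <- rbind(
    make_record("TPXY", T_K = 300, p_bar = sum(pp0), x1 = 0.5, x2 = 0.5,
                y1 = 0.5, y2 = 0.5),
    make_record("TPX", T_K = 300, p_bar = sum(pp0), x1 = 0.5, x2 = 0.5),
    make_record("ACI", T_K = 300, solute_idx = 1L, ln_gamma_inf = 2),
    make_record("HE", T_K = 300, x1 = 0.5, x2 = 0.5, hE_J_mol = 0))
  l0 <- data_losses(stub, sm, rec0, comps)
  expect_equal(l0$TPXY, 0, tolerance = 1e-12)
  expect_equal(l0$TPX, 0, tolerance = 1e-12)
  expect_equal(l0$ACI, 0, tolerance = 1e-12)
  expect_equal(l0$HE, 0, tolerance = 1e-12)
  expect_error(data_losses(stub, sm,
                           make_record("XYZ", T_K = 300, x1 = 0.5), comps),
               "unknown record type")
})

test_that("Gibbs loss is 4 for ideal curves, 0 for demixing, masked in LLE", {
  E <- random_embeddings(2, seed = 42)
  comps <- pair_components(E)
  sm <- surrogate_network(seed = 1)
  lle <- rbind(
    make_record("LLE", T_K = 300, x1p = 0.1, x1pp = 0.9,
                phase_flags = "both"),
    make_record("LLE", T_K = 330, x1p = 0.1, x1pp = 0.9,
                phase_flags = "both"))
  ideal <- gibbsnn_stub(constant_q(0), D = 8)
  li <- data_losses(ideal, sm, lle, comps)
  expect_equal(li$Gibbs, 8, tolerance = 1e-10)  # 4 per record
  expect_equal(li$LLE, 0)                       # masked: no gap predicted
  expect_equal(gibbs_loss(ideal, lle, comps), 8, tolerance = 1e-10)
  demix <- gibbsnn_stub(constant_q(2.5), D = 8)
  ld <- data_losses(demix, sm, lle, comps)
  expect_equal(ld$Gibbs, 0)                     # S_min = -1 < 0
  expect_gt(ld$LLE, 0)                          # unmasked, surrogate active
  expect_equal(gibbs_loss(demix, lle, comps), 0)
})

test_that("ten folds partition systems without leakage, stratified", {
  set.seed(5)
  recs <- do.call(rbind, lapply(1:100, function(i) {
    types <- if (i %% 3 == 0) c("TPXY", "LLE") else c("TPXY", "HE")
    do.call(rbind, lapply(types, function(tp)
      make_record(tp, system_id = sprintf("S%03d", i),
                  component_ids = sprintf("A%03d;B%03d", i, i), T_K = 300)))
  }))
  sp <- split_systems(recs, "tenfold", seed = 7)
  folds <- sp$folds
  tests <- lapply(folds, `[[`, "test")
  expect_identical(sort(unlist(tests)), sort(unique(recs$system_id)))
  expect_identical(anyDuplicated(unlist(tests)), 0L)
  for (f in folds) {
    expect_identical(length(intersect(f$train, f$validation)), 0L)
    expect_identical(length(intersect(f$train, f$test)), 0L)
    expect_identical(length(intersect(f$validation, f$test)), 0L)
    expect_identical(sort(c(f$train, f$validation, f$test)),
                     sort(unique(recs$system_id)))
  }
  # stratification: LLE systems per test fold within +/- 30% of uniform
  lle_sys <- unique(recs$system_id[recs$type == "LLE"])
  share <- length(lle_sys) / 10
  for (tst in tests) {
    n <- length(intersect(tst, lle_sys))
    expect_gte(n, floor(share * 0.7)); expect_lte(n, ceiling(share * 1.3))
  }
  # determinism and error paths
  sp2 <- split_systems(recs, "tenfold", seed = 7)
  expect_identical(sp, sp2)
  expect_error(split_systems(recs[1:9, ], "tenfold", seed = 1), "fewer")
  full <- split_systems(recs, "full", seed = 3)
  expect_identical(length(intersect(full$train, full$validation)), 0L)
  expect_equal(length(full$validation) / 100, 0.05, tolerance = 0.021)
})

test_that("one-cycle schedule warms up to max_lr and anneals below start", {
  lrs <- vapply(1:100, one_cycle_lr, 1, total_steps = 100, max_lr = 0.01)
  expect_equal(max(lrs), 0.01, tolerance = 1e-9)
  expect_equal(which.max(lrs), 30)
  expect_lt(lrs[100], lrs[1])
  expect_true(all(diff(lrs[1:30]) >= 0) && all(diff(lrs[30:100]) <= 0))
})

test_that("a short fit learns, selects after min_epoch, and is seeded", {
  ds <- gibbsnn:::synthetic_dataset(
    10, seed = 51, miscibility_mix = 0.5,
    counts = list(tpxy = 5, tpx = 2, aci = 2, lle = 2, he = 3))
  lab <- surrogate_training_curves(200, seed = 52)
  sm <- train_surrogate(lab, epochs = 25, seed = 53)
  ctl <- gibbsnn_control(width = 12L, epochs = 12L, batch_size = 64L,
                         min_epoch = 5L, seed = 54L)
  fit <- gibbsnn(ds$records, ds$components, surrogate = sm, control = ctl)
  expect_s3_class(fit, "gibbsnn")
  expect_gte(fit$best_epoch, 5L)
  h <- fit$history
  expect_lt(min(h$val_loss[h$epoch >= 5]), h$val_loss[1])
  fit2 <- gibbsnn(ds$records, ds$components, surrogate = sm, control = ctl)
  expect_identical(fit$best_epoch, fit2$best_epoch)
  expect_identical(fit$history$val_loss, fit2$history$val_loss)
  # validation systems never enter training scalers or batches
  expect_true(all(fit$validation_systems %in% ds$records$system_id))
  # the S3 surface
  expect_output(print(fit), "ensemble")
  expect_output(print(summary(fit)), "validation data loss")
  cf <- coef(fit)
  expect_true(all(cf$lipschitz > 0))
  lng <- predict(fit, gibbsnn:::embedding_matrix(ds$components)[, 1:2],
                 c(1, 0), 320)
  expect_lt(abs(lng[1]), 1e-12)
})

test_that("LLE mask and Gibbs loss are mutually exclusive per record", {
  # a record either contributes its Gibbs hinge (no gap predicted) or its
  # masked LLE loss, never both
  E <- random_embeddings(2, seed = 43)
  comps <- pair_components(E)
  sm <- surrogate_network(seed = 2)
  for (A in c(0, 1.5, 2.2, 3)) {
    stub <- gibbsnn_stub(constant_q(A), D = 8)
    rec <- make_record("LLE", T_K = 300, x1p = 0.2, x1pp = 0.8,
                       phase_flags = "both")
    l <- data_losses(stub, sm, rec, comps)
    expect_true(l$Gibbs == 0 || l$LLE == 0)
    if (A > 2) expect_equal(l$Gibbs, 0) else expect_gt(l$Gibbs, 0)
  }
})
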