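# The synthetic data generator: ground-truth consistency, noise-free round
# trips, curation rules, determinism.

test_that("ground-truth providers are internally consistent", {
  for (pv in list(provider_margules(1.8, -150),
                  provider_nrtl(0.9, 120, 1.4, -80, 0.3))) {
    x1 <- seq(0.05, 0.95, by = 0.15)
    h <- 1e-6
    # dgE and d2gE against finite differences of gE
    num1 <- (pv$gE(x1 + h, 320) - pv$gE(x1 - h, 320)) / (2 * h)
    expect_equal(pv$dgE(x1, 320), num1, tolerance = 1e-6)
    num2 <- (pv$gE(x1 + h, 320) - 2 * pv$gE(x1, 320) + pv$gE(x1 - h, 320)) / h^2
    expect_equal(pv$d2gE(x1, 320), num2, tolerance = 1e-3)
    # ln gamma against the thermodynamic identities
    lg <- pv$ln_gamma(x1, 320)
    expect_equal(lg$lng1, pv$gE(x1, 320) + (1 - x1) * pv$dgE(x1, 320),
                 tolerance = 1e-10)
    expect_equal(lg$lng2, pv$gE(x1, 320) - x1 * pv$dgE(x1, 320),
                 tolerance = 1e-10)
    # hE against the Gibbs-Helmholtz finite difference
    hT <- 0.01
    num3 <- -8.31446 * 320^2 * (pv$gE(0.4, 320 + hT) - pv$gE(0.4, 320 - hT)) /
      (2 * hT)
    expect_equal(pv$hE(0.4, 320), num3, tolerance = 1e-4 * max(abs(num3), 1))
  }
  expect_error(provider_nrtl(1, 0, 1, 0, alpha = 0.7), "alpha")
})

test_that("requested demixing fraction is met exactly for Margules", {
  for (mix in c(0, 0.4, 1)) {
    ss <- sample_systems(20, seed = 61, miscibility_mix = mix)
    expect_identical(sum(ss$systems$demixing), as.integer(round(20 * mix)))
    # demixing criterion: A(T) > 2 somewhere in 273-428 K
    for (k in 1:20) {
      A <- function(T) ss$systems$a[k] + ss$systems$b[k] / T
      has <- max(A(273), A(428)) > 2
      expect_identical(has, ss$systems$demixing[k])
    }
  }
  # the stated closed-form threshold: a = 0, b = 625 demixes below 312.5 K
  expect_true(0 + 625 / 312 > 2 && 0 + 625 / 313 < 2)
})

test_that("system sampling is deterministic and embedding-linked", {
  s1 <- sample_systems(12, seed = 62)
  s2 <- sample_systems(12, seed = 62)
  expect_identical(s1$systems$a, s2$systems$a)
  expect_identical(s1$components, s2$components)
  s3 <- sample_systems(12, seed = 63)
  expect_false(identical(s1$systems$a, s3$systems$a))
})

test_that("noise-free records are exactly consistent with the ground truth", {
  ss <- sample_systems(6, seed = 64, miscibility_mix = 0.5)
  zero <- list(ln_gamma = 0, x_lle = 0, hE = 0, ln_p = 0, y = 0)
  k <- which(ss$systems$demixing)[1]
  recs <- generate_records(ss$systems[k, ], ss$components,
                           counts = list(tpxy = 5, tpx = 3, aci = 4, lle = 3,
                                         he = 5),
                           noise = zero, seed = 65, one_phase_frac = 0)
  pv <- ss$systems$provider[[k]]
  ids <- strsplit(ss$systems$component_ids[k], ";")[[1]]
  ant <- as.matrix(ss$components[match(ids, ss$components$component_id),
                                 c("antoine_a", "antoine_b", "antoine_c")])
  tp <- recs[recs$type == "TPXY", ]
  for (i in seq_len(nrow(tp))) {
    ps <- antoine_psat(ant, tp$T_K[i])
    gam <- tp$p_bar[i] * c(tp$y1[i], tp$y2[i]) /
      (ps * c(tp$x1[i], tp$x2[i]))
    lg <- pv$ln_gamma(tp$x1[i], tp$T_K[i])
    expect_equal(unname(log(gam)), c(lg$lng1, lg$lng2), tolerance = 1e-10)
  }
  ac <- recs[recs$type == "ACI", ]
  for (i in seq_len(nrow(ac))) {
    lg <- pv$ln_gamma(ac$x1[i], ac$T_K[i])
    tru <- if (ac$solute_idx[i] == 1L) lg$lng1 else lg$lng2
    expect_equal(ac$ln_gamma_inf[i], tru, tolerance = 1e-10)
  }
  he <- recs[recs$type == "HE", ]
  expect_equal(he$hE_J_mol, pv$hE(he$x1, he$T_K), tolerance = 1e-10)
  # LLE endpoints satisfy isoactivity for both components
  ll <- recs[recs$type == "LLE", ]
  expect_gt(nrow(ll), 0)
  for (i in seq_len(nrow(ll))) {
    lga <- pv$ln_gamma(ll$x1p[i], ll$T_K[i])
    lgb <- pv$ln_gamma(ll$x1pp[i], ll$T_K[i])
    expect_lt(abs(ll$x1p[i] * exp(lga$lng1) - ll$x1pp[i] * exp(lgb$lng1)), 1e-8)
    expect_lt(abs((1 - ll$x1p[i]) * exp(lga$lng2) -
                  (1 - ll$x1pp[i]) * exp(lgb$lng2)), 1e-8)
  }
})

test_that("hE closed form matches the stated value", {
  pv <- provider_margules(0, 100)
  expect_equal(pv$hE(0.5, 300), 207.86, tolerance = 1e-4)
})

test_that("fully miscible systems yield no LLE records", {
  ss <- sample_systems(6, seed = 66, miscibility_mix = 0)
  expect_message(
    recs <- generate_records(ss$systems[1, ], ss$components,
                             counts = list(lle = 3), seed = 67),
    "miscible")
  expect_identical(nrow(recs), 0L)
})

test_that("curation applies the pressure cutoffs and the ternary rule", {
  recs <- rbind(
    make_record("TPXY", T_K = 300, p_bar = 12, x1 = 0.5, x2 = 0.5,
                y1 = 0.5, y2 = 0.5),
    make_record("TPXY", T_K = 300, p_bar = 8, x1 = 0.5, x2 = 0.5,
                y1 = 0.5, y2 = 0.5),
    make_record("TPX", T_K = 300, p_bar = 11, x1 = 0.5, x2 = 0.5),
    make_record("LLE", T_K = 300, p_bar = 40, x1p = 0.1, x1pp = 0.9,
                phase_flags = "both"),
    make_record("LLE", T_K = 300, p_bar = 55, x1p = 0.1, x1pp = 0.9,
                phase_flags = "both"))
  out <- curate(recs)
  expect_identical(out$type, c("TPXY", "LLE"))
  expect_identical(out$p_bar, c(8, 40))
  # ternary infinite-dilution rule
  tern <- function(sys, x1, x2, val, T = 300)
    make_record("ACI", system_id = sys, component_ids = "A;B;C", T_K = T,
                x1 = x1, x2 = x2, solute_idx = 3L, ln_gamma_inf = val)
  # pure solvent A endpoint (x2 = 0) references the binary solute-in-A data
  bin_ref <- make_record("ACI", system_id = "bAC", component_ids = "A;C",
                         T_K = 302, solute_idx = 2L, ln_gamma_inf = 1.00)
  good <- rbind(tern("t1", 0.5, 0.5, 1.5),   # mixed-solvent point, kept
                tern("t1", 1, 0, 1.05),      # endpoint: dev 0.05 <= 0.1, ok
                bin_ref)
  out2 <- curate(good)
  expect_true(any(out2$system_id == "t1" & out2$x1 == 0.5))
  expect_false(any(out2$system_id == "t1" & out2$x1 == 1))  # endpoints culled
  bad_dev <- rbind(tern("t2", 0.5, 0.5, 1.5), tern("t2", 1, 0, 1.25), bin_ref)
  expect_false(any(curate(bad_dev)$system_id == "t2"))      # dev 0.25 > 0.1
  no_ref <- rbind(tern("t3", 0.5, 0.5, 1.5), tern("t3", 1, 0, 1.0))
  expect_false(any(curate(no_ref)$system_id == "t3"))       # no reference
  # idempotence
  all_recs <- rbind(recs, good, bad_dev)
  expect_identical(curate(curate(all_recs)), curate(all_recs))
})

test_that("record files round-trip and are byte-stable under a seed", {
  ds <- gibbsnn:::synthetic_dataset(4, seed = 68, miscibility_mix = 0.5,
                                    counts = list(tpxy = 2, tpx = 1, aci = 1,
                                                  lle = 1, he = 1))
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_records(ds$records, f1)
  back <- read_records(f1)
  expect_equal(back$T_K, ds$records$T_K, tolerance = 1e-12)
  expect_identical(back$type, ds$records$type)
  expect_identical(back$phase_flags, ds$records$phase_flags)
  ds2 <- gibbsnn:::synthetic_dataset(4, seed = 68, miscibility_mix = 0.5,
                                     counts = list(tpxy = 2, tpx = 1, aci = 1,
                                                   lle = 1, he = 1))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_records(ds2$records, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(read_records(withr::local_tempfile(lines = "a,b\n1,2")),
               "lacks columns")
})
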