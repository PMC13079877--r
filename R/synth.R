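# Synthetic datasets with known ground truth.
#
# Fictitious components carry hash-seeded embeddings; each binary system's
# classical-model parameters are smooth functions of those embeddings
# (projections through a fixed seeded linear map).  This link is what makes
# the learning task solvable: a model can only generalize from molecular
# embeddings to mixture behavior if such a relationship exists, emulating
# the premise that mixture properties are predictable from molecular
# structure.  Record structure mirrors the five experimental data types.

RECORD_COLUMNS <- c("type", "system_id", "component_ids", "T_K", "p_bar",
                    "x1", "x2", "x3", "y1", "y2", "x1p", "x1pp",
                    "phase_flags", "ln_gamma_inf", "solute_idx", "hE_J_mol")

empty_records <- function() {
  df <- as.data.frame(stats::setNames(
    rep(list(numeric(0)), length(RECORD_COLUMNS)), RECORD_COLUMNS))
  for (nm in c("type", "system_id", "component_ids", "phase_flags"))
    df[[nm]] <- character(0)
  df$solute_idx <- integer(0)
  df
}

record_row <- function(...) {
  vals <- list(...)
  row <- stats::setNames(as.list(rep(NA_real_, length(RECORD_COLUMNS))),
                         RECORD_COLUMNS)
  row$type <- NA_character_; row$system_id <- NA_character_
  row$component_ids <- NA_character_; row$phase_flags <- NA_character_
  row[names(vals)] <- vals
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Draw ground-truth binary systems linked to component embeddings
#'
#' Component pairs are drawn from a pool of synthetic components; each
#' pair's model parameters come from fixed seeded linear projections of the
#' two embeddings (symmetric in the pair).  A calibrated squashing places
#' exactly the requested fraction of Margules systems in the demixing regime
#' (interaction `A(T) = a + b/T` exceeding 2 somewhere in 273-428 K); for
#' NRTL systems the same construction is applied to the critical interaction
#' strength of the symmetric case.
#'
#' @param n_systems number of binary systems
#' @param seed integer seed
#' @param miscibility_mix fraction of systems in the demixing regime
#' @param model `"margules"` (default) or `"nrtl"`
#' @param D embedding dimension of the synthetic components
#' @param dead_zone half-width of the excluded score band around the
#'   miscibility threshold: candidate pairs whose interaction score falls
#'   within it are not selected, so every system is decisively miscible or
#'   decisively demixing (near-critical ambient systems are rare in
#'   practice, and a smooth model cannot be expected to resolve the
#'   razor's edge)
#' @return list with `components` (frame, including Antoine coefficients)
#'   and `systems` (data frame with ids and model parameters; each row also
#'   carries a ready `gamma_provider` in the list column `provider`)
#' @export
sample_systems <- function(n_systems, seed = 1L, miscibility_mix = 0.4,
                           model = c("margules", "nrtl"), D = 16L,
                           dead_zone = 0.15) {
  stopifnot(n_systems >= 1L, miscibility_mix >= 0, miscibility_mix <= 1)
  model <- match.arg(model)
  # fixed random projections: the embedding -> parameter map
  U <- with_seed(child_seed(seed, "map"),
                 matrix(stats::rnorm(3L * D), 3L, D)) / sqrt(D)
  # grow the component pool until both sides of the dead zone have enough
  # candidate pairs
  m <- 2L
  while (choose(m, 2L) < max(2 * n_systems, n_systems + 20L)) m <- m + 1L
  n_up <- round(n_systems * miscibility_mix)
  repeat {
    comps <- synthetic_components(m, D = D, seed = seed)
    E <- embedding_matrix(comps)
    cand <- utils::combn(m, 2L)
    score <- function(pp) {
      # squared differences: a distance-like interaction feature that a
      # sum-aggregating deep set can represent exactly (and smoothly),
      # unlike elementwise absolute differences
      feat_d <- (E[, pp[1L, ], drop = FALSE] - E[, pp[2L, ], drop = FALSE])^2
      feat_s <- E[, pp[1L, ], drop = FALSE] + E[, pp[2L, ], drop = FALSE]
      # standardized over the candidate population so the score spread does
      # not depend on the draw of the projection vectors
      std <- function(z) unname((z - mean(z)) / max(stats::sd(z), 1e-12))
      list(s1 = tanh(std(drop(U[1L, ] %*% feat_d))),
           s2 = tanh(std(drop(U[2L, ] %*% feat_s))),
           s3 = tanh(std(drop(U[3L, ] %*% feat_d))))
    }
    sc_all <- score(cand)
    thr <- if (miscibility_mix <= 0) max(sc_all$s1) + dead_zone
           else if (miscibility_mix >= 1) min(sc_all$s1) - dead_zone
           else stats::quantile(sc_all$s1, 1 - miscibility_mix, names = FALSE)
    up <- which(sc_all$s1 > thr + dead_zone)
    lo <- which(sc_all$s1 < thr - dead_zone)
    if (length(up) >= n_up && length(lo) >= n_systems - n_up) break
    if (m > 8L * (2L + floor(sqrt(2 * n_systems))))
      stop("dead zone too wide for any reasonable candidate pool")
    m <- m + 2L
  }
  sel <- with_seed(child_seed(seed, "pairs"), {
    c(sample(up, n_up), sample(lo, n_systems - n_up))
  })
  sel <- sel[with_seed(child_seed(seed, "order"), sample.int(length(sel)))]
  pairs <- cand[, sel, drop = FALSE]
  s1 <- sc_all$s1[sel]; s2 <- sc_all$s2[sel]; s3 <- sc_all$s3[sel]

  ids <- comps$component_id
  sys_id <- sprintf("S%03d", seq_len(n_systems))
  comp_ids <- paste(ids[pairs[1L, ]], ids[pairs[2L, ]], sep = ";")

  if (model == "margules") {
    b <- 400 * s2
    # squash width balances two generator requirements: demixing systems
    # get interactions clearly above the critical value (resolvable gaps),
    # while the embedding -> parameter surface stays smooth enough for a
    # Lipschitz-constrained model to learn
    A_max <- 2 + 1.5 * tanh((s1 - thr) / 0.3)
    # anchor the squashed value at the temperature where A(T) is largest in
    # 273-428 K, so demixing there <=> s1 > thr exactly
    a <- ifelse(b >= 0, A_max - b / 273, A_max - b / 428)
    systems <- data.frame(system_id = sys_id, component_ids = comp_ids,
                          model = "margules", a = a, b = b,
                          demixing = s1 > thr, stringsAsFactors = FALSE)
    systems$provider <- lapply(seq_len(n_systems), function(k)
      provider_margules(a[k], b[k]))
  } else {
    alpha <- 0.2 + 0.2 * stats::plogis(2 * s3)
    tau_crit <- vapply(alpha, nrtl_critical_tau, 1)
    tsum <- 2 * tau_crit * (1 + 0.6 * tanh((s1 - thr) / 0.3))
    rho <- exp(0.2 * s2)
    a12 <- tsum / (1 + rho); a21 <- tsum * rho / (1 + rho)
    b12 <- 120 * s2; b21 <- -120 * s2
    a12 <- a12 - b12 / 350; a21 <- a21 - b21 / 350  # anchor tau(350 K)
    systems <- data.frame(system_id = sys_id, component_ids = comp_ids,
                          model = "nrtl", a12 = a12, b12 = b12, a21 = a21,
                          b21 = b21, alpha = alpha, demixing = s1 > thr,
                          stringsAsFactors = FALSE)
    systems$provider <- lapply(seq_len(n_systems), function(k)
      provider_nrtl(a12[k], b12[k], a21[k], b21[k], alpha[k]))
  }
  list(components = comps, systems = systems)
}

# Critical symmetric NRTL interaction: smallest tau (= tau12 = tau21) whose
# stability minimum reaches zero for the given nonrandomness alpha.
nrtl_critical_tau <- function(alpha) {
  f <- function(tau)
    stability_min(provider_nrtl(tau, 0, tau, 0, alpha), 300)$S_min
  stats::uniroot(f, c(0.5, 6), tol = 1e-10)$root
}

default_noise <- function() {
  list(ln_gamma = 0.02, x_lle = 0.005, hE = 10, ln_p = 0.01, y = 0.005)
}

# 95% of temperatures uniform in [273, 428] K, 5% in the adjacent tails.
sample_temperatures <- function(n) {
  tail <- stats::runif(n) < 0.05
  ifelse(tail,
         ifelse(stats::runif(n) < 0.5, stats::runif(n, 243, 273),
                stats::runif(n, 428, 458)),
         stats::runif(n, 273, 428))
}

#' Generate synthetic records for one system
#'
#' Draws state points, evaluates the system's closed-form ground truth, and
#' assembles the five record types with additive/multiplicative noise:
#' VLE records through the extended Raoult's law and Antoine vapor
#' pressures, infinite-dilution records from the closed-form limits, LLE
#' records from the exact common-tangent construction (with a configurable
#' fraction reporting only one phase, as is typical of experimental
#' collections), and excess-enthalpy records from the Gibbs-Helmholtz
#' closed form.
#'
#' @param system one row of `sample_systems()$systems` (data frame or list)
#' @param components the components frame from [sample_systems()]
#' @param counts named list of record counts per type, e.g.
#'   `list(tpxy = 35, tpx = 35, aci = 4, lle = 13, he = 27)` — the per-system data densities typical of the large experimental collections this pipeline emulates
#' @param noise named list of noise levels (see defaults in the source:
#'   sd 0.02 on ln gamma, 0.005 on LLE fractions, 10 J/mol on hE, 0.01 on
#'   ln p, 0.005 on vapor fractions); pass 0s for noise-free data
#' @param seed integer seed
#' @param one_phase_frac fraction of LLE records reporting one phase only
#' @return records data frame (possibly with zero LLE rows if the system is
#'   fully miscible over the sampled temperatures)
#' @export
generate_records <- function(system, components,
                             counts = list(tpxy = 35, tpx = 35, aci = 4,
                                           lle = 13, he = 27),
                             noise = default_noise(), seed = 1L,
                             one_phase_frac = 0.75) {
  if (is.data.frame(system)) system <- as.list(system[1L, ])
  pv <- if (inherits(system$provider, "gamma_provider")) system$provider
        else system$provider[[1L]]
  noise <- utils::modifyList(default_noise(), as.list(noise))
  ids <- strsplit(system$component_ids, ";")[[1]]
  ci <- match(ids, components$component_id)
  ant <- as.matrix(components[ci, c("antoine_a", "antoine_b", "antoine_c")])
  out <- list()

  with_seed(child_seed(seed, paste0("records-", system$system_id)), {
    base <- list(system_id = system$system_id,
                 component_ids = system$component_ids)

    nv <- counts$tpxy %||% 0
    if (nv > 0) {
      T <- sample_temperatures(nv)
      x1 <- stats::runif(nv, 0.02, 0.98)
      lg <- pv$ln_gamma(x1, T)
      ps <- cbind(antoine_psat(ant[1L, ], T), antoine_psat(ant[2L, ], T))
      pp1 <- ps[, 1L] * x1 * exp(lg$lng1)
      pp2 <- ps[, 2L] * (1 - x1) * exp(lg$lng2)
      p <- (pp1 + pp2) * exp(stats::rnorm(nv, 0, noise$ln_p))
      y1 <- pmin(pmax(pp1 / (pp1 + pp2) + stats::rnorm(nv, 0, noise$y),
                      1e-6), 1 - 1e-6)
      for (k in seq_len(nv))
        out[[length(out) + 1L]] <- do.call(record_row, c(base, list(
          type = "TPXY", T_K = T[k], p_bar = p[k], x1 = x1[k], x2 = 1 - x1[k],
          y1 = y1[k], y2 = 1 - y1[k])))
    }

    nv <- counts$tpx %||% 0
    if (nv > 0) {
      T <- sample_temperatures(nv)
      x1 <- stats::runif(nv, 0.02, 0.98)
      lg <- pv$ln_gamma(x1, T)
      p <- (antoine_psat(ant[1L, ], T) * x1 * exp(lg$lng1) +
            antoine_psat(ant[2L, ], T) * (1 - x1) * exp(lg$lng2)) *
        exp(stats::rnorm(nv, 0, noise$ln_p))
      for (k in seq_len(nv))
        out[[length(out) + 1L]] <- do.call(record_row, c(base, list(
          type = "TPX", T_K = T[k], p_bar = p[k], x1 = x1[k], x2 = 1 - x1[k])))
    }

    nv <- counts$aci %||% 0
    if (nv > 0) {
      T <- sample_temperatures(nv)
      solute <- sample(1:2, nv, replace = TRUE)
      for (k in seq_len(nv)) {
        xs <- if (solute[k] == 1L) 0 else 1
        lg <- pv$ln_gamma(xs, T[k])
        tru <- if (solute[k] == 1L) lg$lng1 else lg$lng2
        out[[length(out) + 1L]] <- do.call(record_row, c(base, list(
          type = "ACI", T_K = T[k], x1 = xs, x2 = 1 - xs,
          solute_idx = solute[k],
          ln_gamma_inf = tru + stats::rnorm(1, 0, noise$ln_gamma))))
      }
    }

    nv <- counts$lle %||% 0
    if (nv > 0) {
      # find the demixing temperature window on a coarse scan
      Tscan <- seq(273, 428, by = 5)
      demix <- vapply(Tscan, function(tt)
        stability_min(pv, tt)$S_min < 0, TRUE)
      if (!any(demix)) {
        message(sprintf("system %s: fully miscible over 273-428 K, no LLE records",
                        system$system_id))
      } else {
        Tok <- Tscan[demix]
        for (k in seq_len(nv)) {
          T <- Tok[sample.int(length(Tok), 1L)] + stats::runif(1, -2.5, 2.5)
          ct <- lle_common_tangent(pv, T)
          if (!nrow(ct)) next
          gi <- which.max(ct$x1_doubleprime - ct$x1_prime)
          xp <- ct$x1_prime[gi] + stats::rnorm(1, 0, noise$x_lle)
          xpp <- ct$x1_doubleprime[gi] + stats::rnorm(1, 0, noise$x_lle)
          lohi <- sort(pmin(pmax(c(xp, xpp), 0), 1))
          flags <- if (stats::runif(1) < one_phase_frac)
            sample(c("prime", "doubleprime"), 1L) else "both"
          out[[length(out) + 1L]] <- do.call(record_row, c(base, list(
            type = "LLE", T_K = T, p_bar = 1.013,
            x1p = if (flags != "doubleprime") lohi[1L] else NA_real_,
            x1pp = if (flags != "prime") lohi[2L] else NA_real_,
            phase_flags = flags)))
        }
      }
    }

    nv <- counts$he %||% 0
    if (nv > 0) {
      T <- sample_temperatures(nv)
      x1 <- stats::runif(nv, 0.02, 0.98)
      hE <- pv$hE(x1, T) + stats::rnorm(nv, 0, noise$hE)
      for (k in seq_len(nv))
        out[[length(out) + 1L]] <- do.call(record_row, c(base, list(
          type = "HE", T_K = T[k], x1 = x1[k], x2 = 1 - x1[k],
          hE_J_mol = hE[k])))
    }
  })
  if (!length(out)) return(empty_records())
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a full synthetic dataset
#'
#' Convenience wrapper: draws systems and generates records for all of them.
#'
#' @inheritParams sample_systems
#' @inheritParams generate_records
#' @return list with `components`, `systems`, `records`
#' @export
synthetic_dataset <- function(n_systems, seed = 1L, miscibility_mix = 0.4,
                              model = "margules", D = 16L,
                              counts = list(tpxy = 35, tpx = 35, aci = 4,
                                            lle = 13, he = 27),
                              noise = default_noise(),
                              one_phase_frac = 0.75) {
  ss <- sample_systems(n_systems, seed = seed,
                       miscibility_mix = miscibility_mix, model = model, D = D)
  recs <- lapply(seq_len(nrow(ss$systems)), function(k) {
    cnt <- counts
    if (!ss$systems$demixing[k]) cnt$lle <- 0
    generate_records(ss$systems[k, ], ss$components, counts = cnt,
                     noise = noise, seed = child_seed(seed, k),
                     one_phase_frac = one_phase_frac)
  })
  list(components = ss$components, systems = ss$systems,
       records = do.call(rbind, recs))
}

#' Apply the curation filters
#'
#' Three filters: VLE records (both types) above 10 bar are dropped; LLE
#' records above 50 bar are dropped; ternary infinite-dilution systems are
#' validated against binary references — the reported pure-solvent endpoint
#' values are compared with binary records of the same solute/solvent within
#' +/- 5 K, the whole ternary system is dropped when no reference exists or
#' the absolute deviation exceeds 0.1, and only mixed-solvent points of the
#' retained systems are kept.  Curation is idempotent.
#'
#' @param records records data frame
#' @return the filtered records
#' @export
curate <- function(records) {
  n_comp <- vapply(strsplit(records$component_ids, ";"), length, 1L)
  keep <- rep(TRUE, nrow(records))
  keep[records$type %in% c("TPXY", "TPX") &
         !is.na(records$p_bar) & records$p_bar > 10] <- FALSE
  keep[records$type == "LLE" & !is.na(records$p_bar) &
         records$p_bar > 50] <- FALSE

  tern <- which(records$type == "ACI" & n_comp == 3L)
  if (length(tern)) {
    bin <- records[records$type == "ACI" & n_comp == 2L, , drop = FALSE]
    bad_sys <- character(0)
    ok_sys <- character(0)
    for (i in tern) {
      sid <- records$system_id[i]
      if (sid %in% c(bad_sys, ok_sys)) next
      rows <- records[records$system_id == sid & records$type == "ACI", ,
                      drop = FALSE]
      ids <- strsplit(records$component_ids[i], ";")[[1]]
      solute <- ids[rows$solute_idx[1L]]
      solvents <- setdiff(ids, solute)
      # endpoint rows: one solvent fraction is zero
      ep <- rows[!is.na(rows$x1) & !is.na(rows$x2) &
                   (rows$x1 == 0 | rows$x2 == 0), , drop = FALSE]
      # validation is driven by the reported endpoints; a system without
      # endpoint rows has nothing to check (this keeps curation idempotent)
      ok <- TRUE
      for (j in seq_len(nrow(ep))) {
        solv <- if (ep$x1[j] == 0) solvents[2L] else solvents[1L]
        ref <- bin[vapply(strsplit(bin$component_ids, ";"), function(v)
          all(c(solute, solv) %in% v), TRUE) &
            abs(bin$T_K - ep$T_K[j]) <= 5, , drop = FALSE]
        if (!nrow(ref) ||
            min(abs(ref$ln_gamma_inf - ep$ln_gamma_inf[j])) > 0.1) {
          ok <- FALSE; break
        }
      }
      if (ok) ok_sys <- c(ok_sys, sid) else bad_sys <- c(bad_sys, sid)
    }
    drop_all <- records$system_id %in% bad_sys & records$type == "ACI" &
      n_comp == 3L
    keep[drop_all] <- FALSE
    # retained ternary systems: keep only mixed-solvent points
    endpoint <- records$type == "ACI" & n_comp == 3L &
      records$system_id %in% ok_sys &
      (!is.na(records$x1) & !is.na(records$x2) &
         (records$x1 == 0 | records$x2 == 0))
    keep[endpoint] <- FALSE
  }
  records[keep, , drop = FALSE]
}

#' Read / write records files
#'
#' CSV with the fixed column set `type, system_id, component_ids, T_K,
#' p_bar, x1, x2, x3, y1, y2, x1p, x1pp, phase_flags, ln_gamma_inf,
#' solute_idx, hE_J_mol`; unused cells are empty.
#'
#' @param records records data frame
#' @param path file path
#' @return `read_records` returns the records data frame
#' @export
write_records <- function(records, path) {
  df <- records[, RECORD_COLUMNS]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(RECORD_COLUMNS, names(df))
  if (length(missing)) stop("records file lacks columns: ",
                            paste(missing, collapse = ", "))
  for (nm in c("type", "system_id", "component_ids", "phase_flags")) {
    df[[nm]] <- as.character(df[[nm]])
    df[[nm]][df[[nm]] == "" | is.na(df[[nm]])] <- NA_character_
  }
  df
}
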