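test_that("anchoring standardizes exactly against the anchor set", {
  m <- rbind(f1 = c(1, 2, 3, 10, -4), f2 = c(5, 5, 5, 1, 2),
             f3 = rnorm(5))
  colnames(m) <- paste0("s", 1:5)
  z <- anchor_zscore(m, c("s1", "s2", "s3"))
  # hand computation: anchors {1,2,3} have mean 2, sd 1
  expect_equal(unname(z["f1", 1:3]), c(-1, 0, 1))
  expect_equal(unname(z["f1", "s4"]), 8)
  # constant feature excluded and logged
  expect_false("f2" %in% rownames(z))
  expect_equal(attr(z, "dropped_features"), "f2")
  expect_error(anchor_zscore(m, c("s1", "s2")), class = "placentrace_config_error")

  # anchor-restricted mean/SD of a random matrix is exactly 0/1
  set.seed(1)
  r <- matrix(rnorm(300), 30, 10,
              dimnames = list(paste0("f", 1:30), paste0("s", 1:10)))
  zr <- anchor_zscore(r, paste0("s", 1:4))
  expect_lt(max(abs(rowMeans(zr[, 1:4]))), 1e-12)
  expect_lt(max(abs(apply(zr[, 1:4], 1, sd) - 1)), 1e-12)

  # idempotence: anchoring twice equals once
  zz <- anchor_zscore(zr, paste0("s", 1:4))
  expect_equal(zz, zr, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("longitudinal mixed-model detrending removes the control GA trend", {
  sigs <- signature_set(list(S = sprintf("BG%04d", 1:5)))
  cfg <- blood_sim_config(n_subjects_control = 49, n_subjects_case = 10,
                          samples_per_subject = 5, trend_sd = 0.8,
                          subject_sd = 0.5, noise_sd = 0.7,
                          n_genes_background = 40, planted_shift = 0, seed = 31)
  bl <- simulate_blood_longitudinal(cfg, sigs)
  z <- anchor_zscore(bl$matrix, early_control_anchors(bl$meta))
  zd <- detrend_longitudinal(z, bl$meta)
  ctl <- bl$meta$group == "control"
  # control residuals are uncorrelated with gestational age
  cors <- apply(zd[, ctl], 1, function(x) cor(x, bl$meta$ga_weeks[ctl]))
  expect_lt(mean(abs(cors)), 0.05)
  expect_lt(max(abs(cors)), 0.2)

  # planted quadratic trend recovered pointwise: detrended control means near 0
  ga_bins <- cut(bl$meta$ga_weeks[ctl], 5)
  bin_means <- tapply(colMeans(zd[, ctl]), ga_bins, mean)
  expect_lt(max(abs(bin_means)), 0.1)

  # null trend: subtraction leaves case/control contrast intact
  cfg0 <- blood_sim_config(n_subjects_control = 30, n_subjects_case = 30,
                           trend_sd = 0, subject_sd = 0.3, noise_sd = 0.5,
                           n_genes_background = 20, planted_shift = 1, seed = 32)
  bl0 <- simulate_blood_longitudinal(cfg0, sigs)
  zd0 <- detrend_longitudinal(bl0$matrix, bl0$meta)
  on <- bl0$meta$group != "control" & bl0$meta$ga_weeks >= cfg0$onset_ga
  pfeat <- bl0$map$feature_id[bl0$map$gene_symbols %in% bl0$truth$planted_genes]
  raw_gap <- mean(bl0$matrix[pfeat, on]) - mean(bl0$matrix[pfeat, !on])
  det_gap <- mean(zd0[pfeat, on]) - mean(zd0[pfeat, !on])
  expect_equal(det_gap, raw_gap, tolerance = 0.15)
})

test_that("cross-sectional detrending matches its closed forms", {
  set.seed(41)
  n_ctl <- 60; n_case <- 30
  ga <- c(runif(n_ctl, 25, 40), runif(n_case, 25, 40))
  group <- rep(c("control", "case"), c(n_ctl, n_case))
  meta <- tibble::tibble(sample_id = paste0("s", seq_along(ga)),
                         subject_id = paste0("p", seq_along(ga)),
                         group = group, ga_weeks = ga)
  delta <- 2; sigma <- 0.8
  m <- rbind(
    flat_shift = rnorm(length(ga), 0, sigma) + delta * (group != "control"),
    linear = 3 + 0.5 * ga + c(rnorm(n_ctl, 0, 0), rnorm(n_case, 0, 1)),
    noisy = 1 - 0.2 * ga + rnorm(length(ga), 0, sigma))
  colnames(m) <- meta$sample_id
  z <- detrend_crosssectional(m, meta)
  # exactly linear in controls: zero residual SD -> excluded
  expect_false("linear" %in% rownames(z))
  # slope-0 gene with +delta case shift: detrended case mean ~ delta / resid SD
  case_mean <- mean(z["flat_shift", meta$group != "control"])
  expect_equal(case_mean, delta / sigma, tolerance = 0.15)
  # control samples standardized to mean 0 sd 1 exactly
  ctl <- meta$group == "control"
  expect_lt(max(abs(rowMeans(z[, ctl]))), 1e-8)
  expect_lt(max(abs(apply(z[, ctl], 1, sd) - 1)), 1e-8)
  # detrending linearity: a constant added to every sample is absorbed by
  # the control fit (translation invariance); a constant added to case
  # samples only shifts their output by exactly c/(control residual SD)
  m2 <- m; m2["noisy", ] <- m["noisy", ] + 5
  z2 <- detrend_crosssectional(m2, meta)
  expect_equal(z2["noisy", ], z["noisy", ], tolerance = 1e-10)
  m3 <- m; m3["noisy", !ctl] <- m["noisy", !ctl] + 5
  z3 <- detrend_crosssectional(m3, meta)
  sd_noisy <- sd(m["noisy", ctl] -
                   predict(lm(y ~ ga, data.frame(y = m["noisy", ctl],
                                                 ga = ga[ctl]))))
  expect_equal(unname(z3["noisy", !ctl] - z["noisy", !ctl]),
               rep(5 / sd_noisy, sum(!ctl)), tolerance = 1e-6)
  expect_equal(z3["noisy", ctl], z["noisy", ctl], tolerance = 1e-10)
  # degenerate gestational ages rejected
  meta_bad <- dplyr::mutate(meta, ga_weeks = 30)
  expect_error(detrend_crosssectional(m, meta_bad),
               class = "placentrace_config_error")
})

test_that("GAM detrending anchors to T1 controls and validates basis_dim", {
  sigs <- signature_set(list(S = sprintf("BG%04d", 1:5)))
  cfg <- blood_sim_config(n_subjects_control = 30, n_subjects_case = 20,
                          trend_sd = 0.8, subject_sd = 0.2, noise_sd = 0.6,
                          n_genes_background = 30, planted_shift = 0.8,
                          seed = 51)
  pr <- simulate_proteomics(cfg, sigs)
  expect_error(detrend_gam(pr$matrix, pr$meta, basis_dim = 2),
               class = "placentrace_config_error")
  expect_error(detrend_gam(pr$matrix, pr$meta, basis_dim = 7),
               class = "placentrace_config_error")
  z <- detrend_gam(pr$matrix, pr$meta, basis_dim = 4)
  t1c <- pr$meta$sample_id[pr$meta$group == "control" & pr$meta$window == "T1"]
  expect_lt(max(abs(rowMeans(z[, t1c]))), 1e-8)
  expect_lt(max(abs(apply(z[, t1c], 1, sd) - 1)), 1e-8)
  # residual GA slope in controls is near zero after detrending
  ctl <- pr$meta$group == "control"
  slopes <- apply(z[, ctl], 1, function(x) {
    coef(lm(x ~ pr$meta$ga_weeks[ctl]))[2]
  })
  expect_lt(median(abs(slopes)), 0.03)
})

test_that("feature collapsing picks the right probe and honours exclusions", {
  m <- rbind(P1 = c(10, 10, 10, 10), # CV = 0
             P2 = c(5, 10, 15, 20),  # high CV
             P3 = c(100, 101, 99, 100),
             P4 = c(1, 9, 5, 5))
  colnames(m) <- paste0("s", 1:4)
  map <- tibble::tibble(feature_id = c("P1", "P2", "P3", "P4"),
                        gene_symbols = c("G1", "G1", "G2", "G3;G4"))
  out <- collapse_features(m, map, method = "max_cv")
  expect_equal(attr(out, "collapse_log")$feature_id[
    attr(out, "collapse_log")$gene == "G1"], "P2")
  # single-probe gene passes through unchanged
  expect_equal(unname(out["G2", ]), unname(m["P3", ]))
  # multi-gene feature dropped when requested, expanded otherwise
  expect_true(all(c("G3", "G4") %in% rownames(out)))
  out2 <- collapse_features(m, map, method = "max_cv", drop_multigene = TRUE)
  expect_false(any(c("G3", "G4") %in% rownames(out2)))

  # max variance rule
  mv <- collapse_features(m, map, method = "max_variance")
  expect_equal(attr(mv, "collapse_log")$feature_id[
    attr(mv, "collapse_log")$gene == "G1"], "P2")

  # determinism under input reordering with tied criteria
  m_tie <- rbind(PB = c(1, 2, 3), PA = c(1, 2, 3))
  colnames(m_tie) <- paste0("s", 1:3)
  map_tie <- tibble::tibble(feature_id = c("PB", "PA"), gene_symbols = "G")
  pick1 <- attr(collapse_features(m_tie, map_tie), "collapse_log")$feature_id
  pick2 <- attr(collapse_features(m_tie[2:1, ], map_tie[2:1, ]),
                "collapse_log")$feature_id
  expect_equal(pick1, "PA")
  expect_equal(pick2, "PA")

  # unmapped features are an error
  expect_error(collapse_features(m, map[1:3, ]),
               class = "placentrace_validation_error")
})

test_that("control-only detrending preserves case-control contrasts in expectation", {
  sigs <- signature_set(list(S = sprintf("BG%04d", 1:6)))
  cfg <- blood_sim_config(n_subjects_control = 40, n_subjects_case = 40,
                          trend_sd = 0.6, subject_sd = 0, noise_sd = 0.5,
                          n_genes_background = 20, planted_shift = 1,
                          onset_ga = 10, seed = 61)
  bl <- simulate_blood_longitudinal(cfg, sigs)
  pfeat <- bl$map$feature_id[bl$map$gene_symbols %in% bl$truth$planted_genes]
  case <- bl$meta$group != "control"
  scale <- sqrt(cfg$subject_sd^2 + cfg$noise_sd^2)
  raw_gap <- (mean(bl$matrix[pfeat, case]) -
                mean(bl$matrix[pfeat, !case])) / scale
  for (dial in c("crosssectional", "longitudinal")) {
    zd <- switch(dial,
      crosssectional = detrend_crosssectional(bl$matrix, bl$meta),
      longitudinal = detrend_longitudinal(bl$matrix, bl$meta) / scale)
    gap <- mean(zd[pfeat, case]) - mean(zd[pfeat, !case])
    expect_equal(gap, raw_gap, tolerance = 0.12)
  }
})
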