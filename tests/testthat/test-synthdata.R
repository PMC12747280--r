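test_that("single-cell simulator is deterministic and validates its config", {
  cfg <- sim_config(n_genes = 200, n_cell_types = 3, n_samples_per_group = 3,
                    cells_per_type = list(mean = 40, dispersion = 0.3), seed = 7)
  a <- simulate_single_cell_study(cfg)
  b <- simulate_single_cell_study(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$samples, b$samples)

  expect_error(sim_config(n_genes = 0), class = "placentrace_config_error")
  expect_error(sim_config(frac_de = 1.5), class = "placentrace_config_error")
  expect_error(sim_config(nb_dispersion = 0), class = "placentrace_config_error")
})

test_that("simulated study has the designed structure and filter fodder", {
  cfg <- sim_config(n_genes = 200, n_cell_types = 4, n_samples_per_group = 4,
                    cells_per_type = list(mean = 60, dispersion = 0.3), seed = 2)
  st <- simulate_single_cell_study(cfg)
  expect_s3_class(st, "cell_study")
  expect_true(all(st$counts@x >= 0))
  expect_true(all(st$counts@x == round(st$counts@x)))
  expect_setequal(unique(st$samples$group), c("control", "EOPE", "LOPE"))
  expect_equal(nrow(st$samples), 16)
  # rare cell type present in fewer than 3 samples per group
  rare <- placentrace:::placental_cell_types(4)$cell_type[4]
  per_group <- st$cells |>
    dplyr::filter(cell_type == rare) |>
    dplyr::distinct(sample, group) |>
    dplyr::count(group)
  expect_true(all(per_group$n < 3))
  # some combinations at or under 20 cells
  combo_sizes <- dplyr::count(st$cells, cell_type, sample)
  expect_true(any(combo_sizes$n <= 20))
  # origin labels deterministic per cell type
  ori <- dplyr::distinct(st$cells, cell_type, origin)
  expect_equal(nrow(ori), length(unique(st$cells$cell_type)))
})

test_that("null config produces no group-dependent expectation", {
  st <- small_sim_study(seed = 5, frac_de = 0, n_genes = 400, n_per_group = 5)
  expect_equal(nrow(st$truth), 0)
  pb <- aggregate_pseudobulk(qc_filter_cells(st, min_genes = 20))
  de <- fit_de(pb, "wholePE")
  frac <- mean(de$raw_p < 0.05, na.rm = TRUE)
  # binomial band around 0.05 for ~800 tests
  expect_gt(frac, 0.030)
  expect_lt(frac, 0.075)
})

test_that("planted log2fc=2 yields pseudo-bulk case/control ratio near 4", {
  # Monte-Carlo oracle: the mean of NB draws at mean mu*4 over draws at mu
  set.seed(99)
  mu <- 0.5
  oracle_ratio <- mean(rnbinom(1e5, mu = 4 * mu, size = 2.5)) /
    mean(rnbinom(1e5, mu = mu, size = 2.5))
  expect_equal(oracle_ratio, 4, tolerance = 0.05)

  cfg <- sim_config(n_genes = 2000, n_cell_types = 2, n_samples_per_group = 6,
                    cells_per_type = list(mean = 120, dispersion = 0.2),
                    frac_de = 0.05, log2fc_de = 2, prop_up = 1,
                    batch_sd = 0, seed = 13)
  st <- simulate_single_cell_study(cfg)
  pb <- aggregate_pseudobulk(st)
  cpm <- sweep(pb$counts, 2, colSums(pb$counts), "/") * 1e6
  ratios <- purrr::map_dbl(unique(st$truth$cell_type), function(ct) {
    genes <- st$truth$gene[st$truth$cell_type == ct & st$truth$log2fc == 2]
    idx <- pb$combos$cell_type == ct
    case <- pb$combos$combo[idx & pb$combos$group != "control"]
    ctl <- pb$combos$combo[idx & pb$combos$group == "control"]
    mean(rowMeans(cpm[genes, case, drop = FALSE])) /
      mean(rowMeans(cpm[genes, ctl, drop = FALSE]))
  })
  expect_equal(mean(ratios), 4, tolerance = 0.35)
})

test_that("blood simulator honours its degenerate and null cases", {
  sigs <- sig_fixture()
  # noise-free, trend-free: matrix is exactly planted shifts and zeros
  cfg0 <- blood_sim_config(n_subjects_control = 4, n_subjects_case = 4,
                           samples_per_subject = 3, trend_sd = 0,
                           subject_sd = 0, noise_sd = 0, planted_shift = 2,
                           onset_ga = 20, n_genes_background = 30, seed = 1)
  bl <- simulate_blood_longitudinal(cfg0, sigs)
  planted <- bl$truth$planted_genes
  on <- bl$meta$group != "control" & bl$meta$ga_weeks >= 20
  pfeat <- bl$map$feature_id[bl$map$gene_symbols %in% planted]
  expect_true(all(bl$matrix[pfeat, on] == 2))
  expect_true(all(bl$matrix[pfeat, !on] == 0))
  expect_true(all(bl$matrix[setdiff(rownames(bl$matrix), pfeat), ] == 0))

  # zero shift: case and control distributions indistinguishable
  cfg1 <- blood_sim_config(n_subjects_control = 30, n_subjects_case = 30,
                           planted_shift = 0, trend_sd = 0, seed = 4)
  bl1 <- simulate_blood_longitudinal(cfg1, sigs)
  z <- anchor_zscore(bl1$matrix, early_control_anchors(bl1$meta))
  zc <- collapse_features(z, bl1$map)
  sc <- score_signatures(zc, sigs, meta = bl1$meta)
  sc1 <- sc[sc$signature == "SIG_A" & !is.na(sc$score), ]
  p <- t.test(sc1$score[sc1$group == "control"],
              sc1$score[sc1$group != "control"])$p.value
  expect_gt(p, 0.01)

  # early-control anchor set is non-empty by construction
  expect_gte(length(early_control_anchors(bl1$meta)), 3)
})

test_that("blood simulator AUC matches the closed-form normal oracle", {
  sigs <- sig_fixture()
  m <- 10 # genes in SIG_A
  target <- 0.78
  delta <- qnorm(target) * sqrt(2 / m) # closed form: AUC = Phi(delta*sqrt(m)/sqrt(2))
  aucs <- purrr::map_dbl(11:13, function(s) {
    cfg <- blood_sim_config(n_subjects_control = 50, n_subjects_case = 50,
                            trend_sd = 0, subject_sd = 0, noise_sd = 1,
                            planted_shift = delta, onset_ga = 20, seed = s)
    bl <- simulate_blood_longitudinal(cfg, sigs)
    z <- anchor_zscore(bl$matrix, early_control_anchors(bl$meta))
    zc <- collapse_features(z, bl$map)
    sc <- score_signatures(zc, sigs, meta = bl$meta)
    diag <- select_diagnosis_samples(
      sc[sc$signature == "SIG_A" & !is.na(sc$score), ],
      lo = 20, hi = 42, keep = "latest")
    expect_equal(nrow(diag), 100) # one per subject
    roc_auc(diag$score, diag$group != "control")$auc
  })
  # mean over replicate 50/50 studies controls the Monte-Carlo error of a
  # single draw (SD ~ 0.05) while testing the estimator at the stated size
  expect_equal(mean(aucs), target, tolerance = 0.05 / 0.78)
})

test_that("proteomics simulator partitions windows and includes a multi-gene aptamer", {
  sigs <- sig_fixture()
  cfg <- blood_sim_config(n_subjects_control = 10, n_subjects_case = 10,
                          n_genes_background = 40, seed = 6)
  pr <- simulate_proteomics(cfg, sigs)
  expect_true(all(pr$meta$window %in% c("T1", "T2", "T3")))
  expect_equal(nrow(pr$meta), 20 * 3)
  expect_true(any(grepl(";", pr$map$gene_symbols)))
  # duplicate-gene aptamers exist
  first_gene <- sub(";.*$", "", pr$map$gene_symbols)
  expect_true(any(duplicated(first_gene)))
  # window assignment helper flags out-of-window samples
  expect_equal(assign_window(c(10, 15, 22, 30, 42, 42.5)),
               c("none", "T1", "T2", "T3", "T3", "none"))
})

test_that("zero planted proteomic shift gives uniform window t-test p-values", {
  sigs <- signature_set(list(S = sprintf("BG%04d", 1:8)))
  ps <- purrr::map_dbl(1:60, function(s) {
    cfg <- blood_sim_config(n_subjects_control = 15, n_subjects_case = 15,
                            planted_shift = 0, trend_sd = 0.3,
                            n_genes_background = 10, seed = s)
    pr <- simulate_proteomics(cfg, sigs)
    zg <- detrend_gam(pr$matrix, pr$meta, basis_dim = 3)
    zc <- collapse_features(zg, pr$map, method = "max_variance",
                            drop_multigene = TRUE)
    sc <- score_signatures(zc, sigs, meta = pr$meta)
    window_ttest(sc, "T2")$p_value
  })
  # calibrated: rejection rate at 0.05 within binomial band; KS against uniform
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lte(mean(ps < 0.05), 0.15)
})

test_that("signature genes absent from a constrained universe raise a named error", {
  sigs <- signature_set(list(S = c("BG0001", "NOT_A_GENE", "BG0002")))
  cfg <- blood_sim_config(n_genes_background = 5, seed = 1,
                          gene_universe = sprintf("BG%04d", 1:5))
  expect_error(simulate_blood_longitudinal(cfg, sigs), "NOT_A_GENE")
  expect_error(simulate_proteomics(cfg, sigs), "NOT_A_GENE")
})
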