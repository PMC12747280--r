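#' Configuration for the synthetic placental single-cell study
#'
#' Defines the generative model behind [simulate_single_cell_study()]: a
#' case/control design with early- and late-onset preeclampsia strata (EOPE,
#' LOPE), gestational-age-matched controls, per-library batch offsets, and
#' planted differentially expressed genes (DEGs) per cell type.
#'
#' Counts are negative binomial with mean/dispersion parameterization
#' `Var = mu + alpha * mu^2` (so `nb_dispersion` is the `alpha` of the NB GLM
#' fitted downstream). Expected per-cell expression of gene *g* in cell type
#' *t* is
#' `mu_g * f_{g,t} * depth_c * 2^(batch + DE effect)`, where `mu_g` is a
#' log-normal gene baseline with mean `baseline_mean`, `f_{g,t}` a mild
#' cell-type profile, `depth_c` a per-cell depth factor, and the DE effect
#' applies only in case samples for the planted genes of that cell type.
#'
#' @param n_genes number of genes (>= 1). The first `n_mito` genes are named
#'   with the mitochondrial prefix `MT-` so QC filters are exercised.
#' @param n_cell_types number of cell types (2..12); named after placental
#'   populations (CTB, EVT, STB, decidual, stromal, NK, macrophage, ...).
#' @param n_samples_per_group samples in each of the four design cells
#'   (EOPE cases, LOPE cases, and one matched control stratum for each), so
#'   the study holds `4 * n_samples_per_group` samples in total.
#' @param cells_per_type list with `mean` and `dispersion` of the negative
#'   binomial number of cells per (sample, cell type) combination.
#' @param baseline_mean expected counts per gene per cell (log-normal mean).
#' @param nb_dispersion NB overdispersion `alpha` (> 0).
#' @param frac_de fraction of genes planted as differential per cell type.
#' @param log2fc_de magnitude of the planted case-vs-control log2 fold change.
#' @param prop_up proportion of planted DEGs that are up-regulated in cases.
#' @param frac_de_onset,log2fc_onset fraction and effect size of genes whose
#'   case effect applies in EOPE only, so the EOPE-LOPE interaction contrast
#'   has planted signal; both default to 0 (no onset-specific genes).
#' @param composition_fc optional named vector of case/control abundance
#'   ratios per cell type (e.g. `c("EVT-1" = 0.5)` plants a two-fold
#'   depletion in cases); unnamed types keep ratio 1.
#' @param batch_sd SD of per-library log2-scale offsets.
#' @param n_libraries number of sequencing libraries; samples are assigned
#'   round-robin within design cells so batches are balanced across groups.
#' @param depth_sd SD (log scale) of the per-cell depth factor.
#' @param n_mito number of mitochondrial (`MT-`) genes.
#' @param seed root RNG seed; identical seed and config give bit-identical
#'   output.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_cell_types = 8,
                       n_samples_per_group = 10,
                       cells_per_type = list(mean = 150, dispersion = 0.3),
                       baseline_mean = 0.2,
                       nb_dispersion = 0.4,
                       frac_de = 0.05,
                       log2fc_de = 1,
                       prop_up = 0.5,
                       frac_de_onset = 0,
                       log2fc_onset = 0,
                       composition_fc = NULL,
                       batch_sd = 0.15,
                       n_libraries = 4,
                       depth_sd = 0.3,
                       n_mito = 10,
                       seed = 1L) {
  if (n_genes < 1 || n_cell_types < 2 || n_samples_per_group < 1) {
    abort("n_genes, n_cell_types and n_samples_per_group must be positive (n_cell_types >= 2).",
          class = "placentrace_config_error")
  }
  if (frac_de < 0 || frac_de > 1 || frac_de_onset < 0 || frac_de_onset > 1) {
    abort("frac_de and frac_de_onset must lie in [0, 1].", class = "placentrace_config_error")
  }
  if (nb_dispersion <= 0) {
    abort("nb_dispersion must be > 0.", class = "placentrace_config_error")
  }
  if (cells_per_type$mean <= 0) {
    abort("cells_per_type$mean must be positive.", class = "placentrace_config_error")
  }
  structure(
    list(
      n_genes = as.integer(n_genes), n_cell_types = as.integer(n_cell_types),
      n_samples_per_group = as.integer(n_samples_per_group),
      cells_per_type = cells_per_type, baseline_mean = baseline_mean,
      nb_dispersion = nb_dispersion, frac_de = frac_de, log2fc_de = log2fc_de,
      prop_up = prop_up, frac_de_onset = frac_de_onset,
      log2fc_onset = log2fc_onset, composition_fc = composition_fc,
      batch_sd = batch_sd, n_libraries = as.integer(n_libraries),
      depth_sd = depth_sd, n_mito = as.integer(min(n_mito, n_genes)),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Canonical placental cell-type names with deterministic maternal/fetal origin.
placental_cell_types <- function(n) {
  pool <- c("CTB-1", "EVT-1", "STB", "CTB-2", "Decidual", "Stromal",
            "NK-1", "Macrophage-1", "T-cell", "Fibroblast", "Monocyte", "B-cell-1")
  origin <- c("fetal", "fetal", "fetal", "fetal", "maternal", "maternal",
              "maternal", "maternal", "maternal", "maternal", "maternal", "maternal")
  if (n > length(pool)) abort("at most 12 cell types are supported.")
  tibble(cell_type = pool[seq_len(n)], origin = origin[seq_len(n)])
}

#' Simulate a placental single-cell case/control study
#'
#' Generates per-cell NB counts for a design with EOPE and LOPE case strata
#' and gestational-age-matched controls, planted DEGs per cell type, library
#' batch offsets, and deliberately sparse corners (combinations with few
#' cells, one cell type observed in fewer than three samples per group) so
#' the downstream pseudo-bulk filters are exercised.
#'
#' @param cfg a [sim_config()].
#' @return A `cell_study`: list with
#'   * `counts` — sparse genes x cells integer matrix,
#'   * `cells` — tibble (barcode, cell_type, sample, group, library, origin),
#'   * `samples` — tibble (sample, group, onset, ga_weeks, subject, library),
#'   * `truth` — tibble of planted effects (cell_type, gene, log2fc,
#'     log2fc_onset) — ground truth for recovery scoring.
#' @export
simulate_single_cell_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(cfg$seed, "single_cell"))

  n_mito <- cfg$n_mito
  genes <- c(sprintf("MT-%d", seq_len(n_mito)),
             sprintf("G%05d", seq_len(cfg$n_genes - n_mito)))
  types <- placental_cell_types(cfg$n_cell_types)

  n <- cfg$n_samples_per_group
  samples <- tibble(
    sample = sprintf("S%03d", seq_len(4L * n)),
    group = rep(c("control", "EOPE", "control", "LOPE"), each = n),
    onset = rep(c("EOPE", "EOPE", "LOPE", "LOPE"), each = n)
  ) |>
    mutate(
      ga_weeks = ifelse(.data$onset == "EOPE", runif(4L * n, 28, 33.9),
                        runif(4L * n, 34, 40)),
      subject = paste0("P", .data$sample),
      library = sprintf("L%02d", (seq_len(4L * n) - 1L) %% cfg$n_libraries + 1L)
    )

  # gene baselines, cell-type profiles, batch offsets
  mu_g <- rlnorm_mean(cfg$n_genes, cfg$baseline_mean, sdlog = 1)
  type_profile <- matrix(exp(rnorm(cfg$n_genes * cfg$n_cell_types, 0, 0.4)),
                         cfg$n_genes, cfg$n_cell_types)
  batch <- setNames(rnorm(cfg$n_libraries, 0, cfg$batch_sd),
                    sprintf("L%02d", seq_len(cfg$n_libraries)))

  # planted DEGs per cell type (shared case effect; optional EOPE-only genes)
  n_de <- round(cfg$frac_de * cfg$n_genes)
  n_onset <- round(cfg$frac_de_onset * cfg$n_genes)
  truth <- map_dfr(seq_len(cfg$n_cell_types), function(t) {
    de_idx <- if (n_de > 0) sample.int(cfg$n_genes, n_de) else integer(0)
    sgn <- if (n_de > 0) ifelse(runif(n_de) < cfg$prop_up, 1, -1) else numeric(0)
    onset_idx <- if (n_onset > 0) sample.int(cfg$n_genes, n_onset) else integer(0)
    bind_rows(
      tibble(cell_type = types$cell_type[t], gene = genes[de_idx],
             log2fc = sgn * cfg$log2fc_de, log2fc_onset = 0),
      tibble(cell_type = types$cell_type[t], gene = genes[onset_idx],
             log2fc = 0, log2fc_onset = cfg$log2fc_onset)
    )
  })

  # expected cells per combination: decaying abundance across cell types,
  # the last type restricted to two samples per design cell (filter fodder)
  abun <- 1.1^(-(seq_len(cfg$n_cell_types) - 1))
  abun[cfg$n_cell_types] <- 0.08
  comp_fc <- rep(1, cfg$n_cell_types)
  if (!is.null(cfg$composition_fc)) {
    hit <- match(names(cfg$composition_fc), types$cell_type)
    if (anyNA(hit)) abort("composition_fc names unknown cell types.")
    comp_fc[hit] <- unname(cfg$composition_fc)
  }
  rare_type <- cfg$n_cell_types
  keep_rare <- samples |> group_by(.data$group) |>
    slice_min(.data$sample, n = 2, with_ties = FALSE) |> pull(.data$sample)

  ti <- tj <- tx <- vector("list", 0L)
  cell_rows <- vector("list", 0L)
  cell_counter <- 0L
  alpha <- cfg$nb_dispersion

  for (s in seq_len(nrow(samples))) {
    smp <- samples[s, ]
    is_case <- smp$group != "control"
    for (t in seq_len(cfg$n_cell_types)) {
      if (t == rare_type && !(smp$sample %in% keep_rare)) next
      lam <- cfg$cells_per_type$mean * abun[t] * if (is_case) comp_fc[t] else 1
      nc <- rnbinom(1, mu = lam, size = 1 / cfg$cells_per_type$dispersion)
      if (nc == 0) next
      eff <- rep(0, cfg$n_genes)
      if (is_case && nrow(truth) > 0) {
        tt <- truth[truth$cell_type == types$cell_type[t], ]
        gi <- match(tt$gene, genes)
        eff[gi] <- eff[gi] + tt$log2fc +
          if (smp$group == "EOPE") tt$log2fc_onset else 0
      }
      mu_base <- mu_g * type_profile[, t] *
        2^(batch[[smp$library]] + eff)
      depth <- exp(rnorm(nc, 0, cfg$depth_sd))
      m <- matrix(
        rnbinom(cfg$n_genes * nc, mu = rep(mu_base, nc) * rep(depth, each = cfg$n_genes),
                size = 1 / alpha),
        nrow = cfg$n_genes, ncol = nc
      )
      nz <- which(m > 0)
      ti[[length(ti) + 1L]] <- ((nz - 1L) %% cfg$n_genes) + 1L
      tj[[length(tj) + 1L]] <- cell_counter + ((nz - 1L) %/% cfg$n_genes) + 1L
      tx[[length(tx) + 1L]] <- m[nz]
      cell_rows[[length(cell_rows) + 1L]] <- tibble(
        barcode = sprintf("c%07d", cell_counter + seq_len(nc)),
        cell_type = types$cell_type[t], sample = smp$sample,
        group = smp$group, library = smp$library, origin = types$origin[t]
      )
      cell_counter <- cell_counter + nc
    }
  }
  cells <- bind_rows(cell_rows)
  counts <- sparseMatrix(
    i = unlist(ti), j = unlist(tj), x = unlist(tx),
    dims = c(cfg$n_genes, cell_counter),
    dimnames = list(genes, cells$barcode)
  )
  new_cell_study(counts, cells, samples, truth = truth)
}

# log-normal draws with a specified arithmetic mean
rlnorm_mean <- function(n, mean, sdlog) {
  exp(rnorm(n, log(mean) - sdlog^2 / 2, sdlog))
}

#' Construct a cell study from components
#'
#' @param counts genes x cells matrix (coerced to sparse); non-negative
#'   integers.
#' @param cells per-cell annotations (barcode, cell_type, sample, plus
#'   whatever else is carried, e.g. group, library, origin).
#' @param samples per-sample metadata (sample, group, onset, ga_weeks,
#'   subject, library).
#' @param truth optional planted-effect bookkeeping.
#' @return A `cell_study`.
#' @export
cell_study <- function(counts, cells, samples, truth = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(colnames(counts))) colnames(counts) <- cells$barcode
  new_cell_study(counts, cells, samples, truth)
}

new_cell_study <- function(counts, cells, samples, truth = NULL) {
  if (!all(cells$sample %in% samples$sample)) {
    bad <- setdiff(unique(cells$sample), samples$sample)
    abort(paste0("cells reference unknown sample(s): ", paste(bad, collapse = ", ")),
          class = "placentrace_validation_error")
  }
  if (ncol(counts) != nrow(cells)) {
    abort("counts columns and cell annotations disagree in length.",
          class = "placentrace_validation_error")
  }
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    abort("counts must be non-negative integers.",
          class = "placentrace_validation_error")
  }
  structure(list(counts = counts, cells = as_tibble(cells),
                 samples = as_tibble(samples), truth = truth),
            class = "cell_study")
}

#' @export
print.cell_study <- function(x, ...) {
  cat("<cell_study> ", nrow(x$counts), " genes x ", ncol(x$counts), " cells; ",
      nrow(x$samples), " samples; ",
      length(unique(x$cells$cell_type)), " cell types\n", sep = "")
  invisible(x)
}
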