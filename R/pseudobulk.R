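#' Quality-control filter on cells
#'
#' Removes cells with fewer than `min_genes` detected genes (strictly fewer:
#' a cell with exactly `min_genes` is retained) or with a mitochondrial read
#' fraction strictly exceeding `max_mito_frac` (a cell at exactly the
#' threshold is retained). Mitochondrial genes are identified by prefix or
#' by an explicit list.
#'
#' @param study a `cell_study`.
#' @param min_genes minimum number of detected (count > 0) genes.
#' @param max_mito_frac maximum tolerated mitochondrial read fraction.
#' @param mito_genes either a prefix string (default `"MT-"`) or a character
#'   vector of gene names.
#' @return The filtered `cell_study`, with a `qc_log` attribute (tibble:
#'   barcode, n_detected, mito_frac, reason) describing removed cells.
#' @export
qc_filter_cells <- function(study, min_genes = 200, max_mito_frac = 0.25,
                            mito_genes = "MT-") {
  stopifnot(inherits(study, "cell_study"))
  counts <- study$counts
  if (length(mito_genes) == 1 && !mito_genes %in% rownames(counts)) {
    mito <- grep(paste0("^", mito_genes), rownames(counts), value = TRUE)
  } else {
    mito <- intersect(mito_genes, rownames(counts))
  }
  n_detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  if (length(mito) == 0) {
    warn("no mitochondrial genes found; mitochondrial filter is a no-op.")
    mito_frac <- rep(0, ncol(counts))
  } else {
    mito_frac <- Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(total, 1)
  }
  drop_genes <- n_detected < min_genes
  drop_mito <- mito_frac > max_mito_frac
  drop <- drop_genes | drop_mito
  if (all(drop)) {
    abort("no cells survive QC filtering.", class = "placentrace_empty_error")
  }
  log <- tibble(
    barcode = colnames(counts)[drop],
    n_detected = as.integer(n_detected[drop]),
    mito_frac = mito_frac[drop],
    reason = dplyr::case_when(
      drop_genes[drop] & drop_mito[drop] ~ "low_genes+high_mito",
      drop_genes[drop] ~ "low_genes",
      TRUE ~ "high_mito"
    )
  )
  out <- new_cell_study(counts[, !drop, drop = FALSE],
                        study$cells[!drop, , drop = FALSE],
                        study$samples, truth = study$truth)
  attr(out, "qc_log") <- log
  out
}

#' Aggregate single cells to pseudo-bulk profiles
#'
#' Sums raw counts over all cells sharing a (cell type, sample) combination,
#' producing one pseudo-bulk column per observed combination. Sums are exact
#' integer sums, so total reads are conserved.
#'
#' @param study a `cell_study` (typically after [qc_filter_cells()]).
#' @return A `pseudobulk` object: list with `counts` (genes x combinations
#'   dense matrix) and `combos` (tibble: combo, cell_type, sample, n_cells,
#'   plus sample metadata columns group, onset, ga_weeks, library).
#' @export
aggregate_pseudobulk <- function(study) {
  stopifnot(inherits(study, "cell_study"))
  cells <- study$cells
  combo_key <- paste(cells$cell_type, cells$sample, sep = "|")
  combos <- cells |>
    count(.data$cell_type, .data$sample, name = "n_cells") |>
    mutate(combo = paste(.data$cell_type, .data$sample, sep = "|")) |>
    left_join(study$samples, by = "sample") |>
    select("combo", "cell_type", "sample", "n_cells", dplyr::everything())
  ind <- sparseMatrix(i = seq_len(nrow(cells)),
                      j = match(combo_key, combos$combo),
                      x = 1, dims = c(nrow(cells), nrow(combos)))
  counts <- as.matrix(study$counts %*% ind)
  dimnames(counts) <- list(rownames(study$counts), combos$combo)
  structure(list(counts = counts, combos = combos, truth = study$truth),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat("<pseudobulk> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " (cell type, sample) combinations\n", sep = "")
  invisible(x)
}

#' Resolve a contrast to case/control sample sets
#'
#' The four contrasts compare: whole PE (EOPE + LOPE cases) against all
#' controls; EOPE cases against their gestational-age-matched controls; LOPE
#' likewise; and the interaction contrast, which uses all samples and tests
#' whether the case effect differs between onset strata.
#'
#' @param samples sample metadata tibble with `sample`, `group`, `onset`.
#' @param contrast one of `"wholePE"`, `"EOPE"`, `"LOPE"`, `"interaction"`.
#' @return List with `case` and `control` sample id vectors and the contrast.
#' @export
contrast_groups <- function(samples, contrast = c("wholePE", "EOPE", "LOPE",
                                                  "interaction")) {
  contrast <- match.arg(contrast)
  ctl <- samples$group == "control"
  case <- !ctl
  if (contrast %in% c("EOPE", "LOPE")) {
    keep <- samples$onset == contrast
    ctl <- ctl & keep
    case <- case & keep & samples$group == contrast
  }
  list(contrast = contrast,
       case = samples$sample[case],
       control = samples$sample[ctl])
}

#' Filter pseudo-bulk combinations for a contrast
#'
#' Combinations with `min_cells` cells or fewer are treated as non-observed
#' (strictly more than `min_cells` cells are required). Cell types observed
#' in fewer than `min_samples` samples in either the case or the control
#' group of the contrast are excluded entirely.
#'
#' @param pb a `pseudobulk` object.
#' @param groups a [contrast_groups()] list (or `NULL` to apply only the
#'   cell-count filter).
#' @param min_cells combinations must have strictly more cells than this.
#' @param min_samples minimum observed samples per group per cell type.
#' @return Filtered `pseudobulk` restricted to the contrast's samples.
#' @export
filter_combinations <- function(pb, groups = NULL, min_cells = 20,
                                min_samples = 3) {
  stopifnot(inherits(pb, "pseudobulk"))
  keep <- pb$combos$n_cells > min_cells
  combos <- pb$combos[keep, , drop = FALSE]
  if (!is.null(groups)) {
    combos <- combos |>
      filter(.data$sample %in% c(groups$case, groups$control)) |>
      mutate(.arm = ifelse(.data$sample %in% groups$case, "case", "control"))
    ok_types <- combos |>
      count(.data$cell_type, .data$.arm) |>
      tidyr::pivot_wider(names_from = ".arm", values_from = "n",
                         values_fill = 0L)
    for (col in c("case", "control")) {
      if (!col %in% names(ok_types)) ok_types[[col]] <- 0L
    }
    ok_types <- ok_types |>
      filter(.data$case >= min_samples, .data$control >= min_samples) |>
      pull(.data$cell_type)
    if (length(ok_types) == 0) {
      abort(paste0("all cell types fail the sample-count filter for contrast ",
                   groups$contrast, "."),
            class = "placentrace_empty_error")
    }
    combos <- combos |> filter(.data$cell_type %in% ok_types) |>
      select(-".arm")
  }
  structure(list(counts = pb$counts[, combos$combo, drop = FALSE],
                 combos = combos, truth = pb$truth),
            class = "pseudobulk")
}

#' Cell-type composition fold changes between two groups
#'
#' Compares the relative abundance of each cell type between two sample
#' groups, either pooling all cells per group or averaging per-sample
#' proportions. The fold change is reported as proportion in `group_a` over
#' proportion in `group_b`; a zero denominator yields `Inf` with a flag
#' rather than silent dropping.
#'
#' @param study a `cell_study`.
#' @param group_a,group_b group labels from `study$samples$group` (vectors
#'   allowed, e.g. `c("EOPE", "LOPE")` for whole PE).
#' @param level `"pooled"` (proportion of all cells in the group) or
#'   `"per_sample"` (mean of per-sample proportions).
#' @return Tibble: cell_type, prop_a, prop_b, fold_change, infinite (logical).
#' @export
composition_foldchange <- function(study, group_a, group_b,
                                   level = c("pooled", "per_sample")) {
  stopifnot(inherits(study, "cell_study"))
  level <- match.arg(level)
  cells <- study$cells |>
    left_join(study$samples |> select("sample", "onset"), by = "sample")
  in_a <- cells$group %in% group_a
  in_b <- cells$group %in% group_b
  if (!any(in_a) || !any(in_b)) {
    abort("both groups must contain cells.", class = "placentrace_empty_error")
  }
  types <- sort(unique(cells$cell_type))
  prop_of <- function(sub) {
    if (level == "pooled") {
      tab <- table(factor(sub$cell_type, levels = types))
      as.numeric(tab) / nrow(sub)
    } else {
      per <- sub |>
        count(.data$sample, .data$cell_type) |>
        group_by(.data$sample) |>
        mutate(p = .data$n / sum(.data$n)) |>
        ungroup() |>
        tidyr::complete(sample = unique(sub$sample),
                        cell_type = types, fill = list(p = 0)) |>
        group_by(.data$cell_type) |>
        summarise(p = mean(.data$p), .groups = "drop")
      per$p[match(types, per$cell_type)]
    }
  }
  pa <- prop_of(cells[in_a, , drop = FALSE])
  pb <- prop_of(cells[in_b, , drop = FALSE])
  tibble(cell_type = types, prop_a = pa, prop_b = pb,
         fold_change = pa / pb, infinite = pb == 0 & pa > 0)
}

#' Concordance of log2 fold changes between platforms
#'
#' Spearman correlation of per-gene log2 fold changes over the genes shared
#' by two analyses (e.g. a single-cell cell type and a bulk study).
#'
#' @param lfc_sc,lfc_bulk data frames with columns `gene` and
#'   `log2_fold_change` (named numeric vectors also accepted).
#' @return Tibble: spearman_rho, p_value, n_genes.
#' @export
concordance_bulk_sc <- function(lfc_sc, lfc_bulk) {
  as_named <- function(x) {
    if (is.data.frame(x)) setNames(x$log2_fold_change, x$gene) else x
  }
  a <- as_named(lfc_sc); b <- as_named(lfc_bulk)
  shared <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
  if (length(shared) == 0) {
    abort("no shared genes between the two fold-change sets.",
          class = "placentrace_empty_error")
  }
  if (length(shared) < 10) {
    warn("fewer than 10 shared genes; concordance estimate is unstable.")
  }
  ct <- suppressWarnings(cor.test(a[shared], b[shared], method = "spearman",
                                  exact = FALSE))
  tibble(spearman_rho = unname(ct$estimate), p_value = ct$p.value,
         n_genes = length(shared))
}
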