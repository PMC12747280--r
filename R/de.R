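#' Pseudo-bulk differential expression by negative binomial GLM
#'
#' Fits, per cell type and per gene, a negative binomial GLM (log link) on
#' size-factor-normalized pseudo-bulk counts with a case/control term and a
#' library (batch) factor, and Wald-tests the case coefficient. Size factors
#' use the median-of-ratios method over genes with positive geometric mean.
#' Per-gene dispersions are estimated in two stages: a method-of-moments
#' start on normalized counts (fallback to the median dispersion when the
#' moment estimate is non-positive), then a Pearson moment re-estimate around
#' the GLM-fitted means with a residual degrees-of-freedom correction, which
#' removes the inflation that group and batch mean structure would otherwise
#' add; there is no empirical-Bayes shrinkage. Wald statistics on the
#' refitted model are referred to the standard normal.
#' P-values are BH-adjusted across genes within each
#' cell type; genes that fail to converge are flagged and excluded from the
#' BH denominator; all-zero genes are skipped.
#'
#' For the `"interaction"` contrast the model crosses case status with onset
#' stratum (EOPE/LOPE) and tests the interaction coefficient, i.e. the
#' difference between the EOPE and LOPE case effects.
#'
#' @param pb a `pseudobulk` object (from [aggregate_pseudobulk()]).
#' @param contrast `"wholePE"`, `"EOPE"`, `"LOPE"` or `"interaction"`.
#' @param min_cells,min_samples combination filters, passed to
#'   [filter_combinations()].
#' @param library_factor include the library batch factor (dropped
#'   automatically when it has a single level).
#' @return A `deg_table` tibble: cell_type, contrast, gene, base_mean,
#'   log2_fold_change, raw_p, fdr, note.
#' @export
fit_de <- function(pb, contrast = c("wholePE", "EOPE", "LOPE", "interaction"),
                   min_cells = 20, min_samples = 3, library_factor = TRUE) {
  stopifnot(inherits(pb, "pseudobulk"))
  contrast <- match.arg(contrast)
  samples <- distinct(pb$combos, .data$sample, .data$group, .data$onset)
  grp <- contrast_groups(samples,
                         if (contrast == "interaction") "wholePE" else contrast)
  grp$contrast <- contrast
  pbf <- filter_combinations(pb, grp, min_cells = min_cells,
                             min_samples = min_samples)
  out <- map_dfr(sort(unique(pbf$combos$cell_type)), function(ct) {
    idx <- pbf$combos$cell_type == ct
    de_one_celltype(pbf$counts[, pbf$combos$combo[idx], drop = FALSE],
                    pbf$combos[idx, , drop = FALSE], contrast, library_factor)
  })
  out$contrast <- contrast
  class(out) <- unique(c("deg_table", class(tibble())))
  out[, c("cell_type", "contrast", "gene", "base_mean", "log2_fold_change",
          "raw_p", "fdr", "note")]
}

# median-of-ratios size factors (over genes with positive geometric mean)
size_factors_mor <- function(counts) {
  logg <- rowMeans(log(counts))
  use <- is.finite(logg)
  if (!any(use)) {
    # fall back to library-size factors when no gene is always positive
    sf <- colSums(counts)
    return(sf / exp(mean(log(sf))))
  }
  apply(counts, 2, function(col) {
    exp(median((log(col) - logg)[use & col > 0]))
  })
}

de_one_celltype <- function(counts, combos, contrast, library_factor) {
  case <- factor(ifelse(combos$group == "control", "control", "case"),
                 levels = c("control", "case"))
  lib <- droplevels(factor(combos$library))
  dat <- data.frame(case = case)
  form <- ~case
  if (contrast == "interaction") {
    dat$onset <- droplevels(factor(combos$onset, levels = c("EOPE", "LOPE")))
    form <- ~ case * onset
  }
  if (library_factor && nlevels(lib) > 1) {
    dat$lib <- lib
    form <- stats::update(form, ~ . + lib)
  }
  X <- model.matrix(form, dat)
  target <- if (contrast == "interaction") "casecase:onsetLOPE" else "casecase"
  j <- match(target, colnames(X))
  if (is.na(j)) abort("contrast coefficient absent from design matrix.")

  sf <- size_factors_mor(counts)
  off <- log(sf)
  q <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(q)
  v <- apply(q, 1, var)
  alpha <- (v - mu * mean(1 / sf)) / mu^2
  alpha[!is.finite(alpha) | alpha <= 0] <- NA_real_
  common <- median(alpha, na.rm = TRUE)
  if (!is.finite(common)) common <- 0.1
  alpha_use <- pmin(pmax(ifelse(is.na(alpha), common, alpha), 1e-8), 100)

  n <- ncol(counts); p <- ncol(X)
  df_resid <- n - p
  nb_fit <- function(y, a) {
    fam <- MASS::negative.binomial(theta = 1 / a, link = "log")
    fit <- tryCatch(
      suppressWarnings(glm.fit(X, y, family = fam, offset = off)),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged || fit$rank < p) NULL else fit
  }
  res <- map_dfr(seq_len(nrow(counts)), function(g) {
    y <- counts[g, ]
    failed <- tibble(gene = rownames(counts)[g], base_mean = mu[g],
                     log2_fold_change = NA_real_, raw_p = NA_real_,
                     note = "no_convergence")
    if (all(y == 0)) {
      return(tibble(gene = rownames(counts)[g], base_mean = 0,
                    log2_fold_change = NA_real_, raw_p = NA_real_,
                    note = "all_zero"))
    }
    fit <- nb_fit(y, alpha_use[g])
    if (is.null(fit)) return(failed)
    # Pearson moment dispersion around fitted means, df-corrected
    fv <- fit$fitted.values
    a2 <- (n / max(df_resid, 1) * sum((y - fv)^2) - sum(fv)) / sum(fv^2)
    a2 <- min(max(a2, 1e-8), 100)
    fit <- nb_fit(y, a2)
    if (is.null(fit)) return(failed)
    cov_un <- tryCatch(chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]),
                       error = function(e) NULL)
    if (is.null(cov_un) || !is.finite(cov_un[j, j]) || cov_un[j, j] <= 0) {
      return(failed)
    }
    est <- fit$coefficients[j]
    zval <- est / sqrt(cov_un[j, j])
    tibble(gene = rownames(counts)[g], base_mean = mu[g],
           log2_fold_change = est / log(2),
           raw_p = 2 * pnorm(-abs(zval)), note = "ok")
  })
  res$fdr <- NA_real_
  ok <- !is.na(res$raw_p)
  res$fdr[ok] <- p.adjust(res$raw_p[ok], method = "BH")
  res$cell_type <- combos$cell_type[1]
  res
}

#' Extract cell-type signatures from a DEG table
#'
#' Signatures are the genes passing the FDR cutoff with the requested sign
#' of the log2 fold change, named `<cellType>_<contrast>`. Empty signatures
#' are dropped with a warning.
#'
#' @param de a `deg_table` from [fit_de()].
#' @param fdr_cut adjusted p-value cutoff (DEGs are `fdr < fdr_cut`).
#' @param direction `"up"` (higher in cases; the default, matching the
#'   assumption that circulating signature scores are higher in cases),
#'   `"down"`, or `"both"` (each gene keeps its own direction label).
#' @return A [signature_set()].
#' @export
extract_signatures <- function(de, fdr_cut = 0.1,
                               direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(de))
  hits <- de |>
    filter(!is.na(.data$fdr), .data$fdr < fdr_cut,
           !is.na(.data$log2_fold_change)) |>
    mutate(gene_dir = ifelse(.data$log2_fold_change > 0, "up", "down"))
  if (direction != "both") hits <- hits |> filter(.data$gene_dir == direction)
  empty <- setdiff(unique(de$cell_type), unique(hits$cell_type))
  if (length(empty) > 0) {
    warn(paste0("no DEGs for cell type(s): ", paste(empty, collapse = ", "),
                "; signature(s) omitted."))
  }
  if (nrow(hits) == 0) {
    abort("no signatures could be extracted at this FDR cutoff.",
          class = "placentrace_empty_error")
  }
  sigs <- hits |>
    mutate(signature = paste(.data$cell_type, .data$contrast, sep = "_")) |>
    select("signature", source = "contrast", direction = "gene_dir", "gene")
  validate_signature_set(sigs)
}

#' Quantile-quantile summary of DE p-values per cell type
#'
#' Orders observed -log10 p-values against uniform expected quantiles; the
#' mean observed-minus-expected gap ranks cell types by transcriptional
#' perturbation (deviation above the identity line reflects enrichment of
#' small p-values).
#'
#' @param de a `deg_table`.
#' @return Tibble (cell_type, expected, observed) with attribute
#'   `"deviation"`: a tibble ranking cell types by mean gap.
#' @export
qq_enrichment <- function(de) {
  stopifnot(is.data.frame(de))
  out <- map_dfr(sort(unique(de$cell_type)), function(ct) {
    p <- de$raw_p[de$cell_type == ct]
    p <- p[!is.na(p)]
    if (length(p) < 10) {
      abort(paste0("fewer than 10 tested genes for cell type ", ct, "."),
            class = "placentrace_empty_error")
    }
    n <- length(p)
    tibble(cell_type = ct,
           expected = -log10((seq_len(n) - 0.5) / n),
           observed = -log10(sort(p)))
  })
  dev <- out |>
    group_by(.data$cell_type) |>
    summarise(mean_gap = mean(.data$observed - .data$expected),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$mean_gap))
  attr(out, "deviation") <- dev
  class(out) <- unique(c("qq_table", class(tibble())))
  out
}

#' @rdname qq_enrichment
#' @param x a `qq_table`.
#' @param ... unused.
#' @export
autoplot.qq_table <- function(x, ...) {
  ggplot(as_tibble(x), aes(.data$expected, .data$observed)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    geom_point(size = 0.5) +
    facet_wrap(~cell_type) +
    labs(x = "expected -log10 p", y = "observed -log10 p") +
    theme_bw()
}
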