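#' Anchor a feature matrix to a reference sample set
#'
#' Standardizes each feature (row) by subtracting the mean and dividing by
#' the sample standard deviation (n-1) computed over a designated anchor set
#' — e.g. control samples collected at or before 11 weeks of gestation, or
#' T1 controls for proteomics — yielding Z-scores on a common scale.
#' Features constant over the anchor set (zero SD) are excluded and logged.
#'
#' @param m numeric matrix, features x samples.
#' @param anchor_samples character vector of anchor sample ids (>= 3).
#' @return Z-score matrix with attributes `provenance` (list) and
#'   `dropped_features` (character).
#' @export
anchor_zscore <- function(m, anchor_samples) {
  stopifnot(is.matrix(m))
  anchor_samples <- intersect(anchor_samples, colnames(m))
  if (length(anchor_samples) < 3) {
    abort("need at least 3 anchor samples.", class = "placentrace_config_error")
  }
  a <- m[, anchor_samples, drop = FALSE]
  mu <- rowMeans(a)
  s <- apply(a, 1, sd)
  keep <- s > 0
  if (!all(keep)) {
    inform(paste0(sum(!keep), " feature(s) constant over the anchor set; excluded."))
  }
  z <- (m[keep, , drop = FALSE] - mu[keep]) / s[keep]
  attr(z, "provenance") <- list(step = "anchor_zscore",
                                anchor_samples = anchor_samples)
  attr(z, "dropped_features") <- rownames(m)[!keep]
  z
}

#' Select anchor samples by gestational age
#'
#' @param meta sample metadata tibble (`sample_id`, `group`, `ga_weeks`).
#' @param max_ga inclusive gestational-age bound in weeks (default 11).
#' @return Character vector of control sample ids at or before `max_ga`.
#' @export
early_control_anchors <- function(meta, max_ga = 11) {
  meta$sample_id[meta$group == "control" & meta$ga_weeks <= max_ga]
}

# shared degree-2 B-spline basis over the full observed GA range, so case
# samples outside the control GA range never hit extrapolation warnings
ga_spline_basis <- function(ga_all, degree = 2) {
  bounds <- range(ga_all)
  function(ga) splines::bs(ga, degree = degree, Boundary.knots = bounds)
}

#' Remove the gestational-age trend estimated in controls (longitudinal)
#'
#' Per gene, fits a linear mixed-effects model on control samples only —
#' fixed-effect degree-2 B-spline of gestational age plus a random intercept
#' per subject — and subtracts the fitted fixed-effect trend (evaluated at
#' each sample's gestational age) from all samples, cases included. A gene
#' whose mixed fit fails falls back to a fixed-effects-only spline fit, and
#' is logged.
#'
#' @param z features x samples matrix (typically an anchored Z matrix).
#' @param meta tibble with `sample_id`, `subject_id`, `group`, `ga_weeks`.
#' @param spline_degree B-spline degree (default 2).
#' @return Residualized matrix; attribute `fallback_features` lists genes
#'   fitted without a random effect.
#' @export
detrend_longitudinal <- function(z, meta, spline_degree = 2) {
  stopifnot(is.matrix(z))
  meta <- meta[match(colnames(z), meta$sample_id), ]
  if (anyNA(meta$sample_id)) abort("metadata missing for some samples.")
  ctl <- meta$group == "control"
  if (!any(ctl)) abort("no control samples to estimate the trend from.")
  basis <- ga_spline_basis(meta$ga_weeks, spline_degree)
  B_ctl <- basis(meta$ga_weeks[ctl])
  B_all <- basis(meta$ga_weeks)
  subj <- factor(meta$subject_id[ctl])
  fallback <- character(0)
  out <- z
  dat0 <- data.frame(subj = subj)
  for (g in seq_len(nrow(z))) {
    y <- z[g, ctl]
    dat <- dat0
    dat$y <- y
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(y ~ B_ctl + (1 | subj), data = dat, REML = TRUE)
      )),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      fe <- lme4::fixef(fit)
      trend <- cbind(1, B_all) %*% fe
    } else {
      fallback <- c(fallback, rownames(z)[g])
      lmfit <- lm.fit(cbind(1, B_ctl), y)
      trend <- cbind(1, B_all) %*% lmfit$coefficients
    }
    out[g, ] <- z[g, ] - as.numeric(trend)
  }
  attr(out, "provenance") <- list(step = "detrend_longitudinal",
                                  spline_degree = spline_degree)
  attr(out, "fallback_features") <- fallback
  out
}

#' Remove the gestational-age trend by control-fitted regression residuals
#'
#' Per gene, regresses expression on gestational age within control samples
#' (polynomial of the configured degree; the default is linear) and converts
#' all samples to residuals relative to the control fit, divided by the
#' control residual standard deviation — the cross-sectional Z-score
#' dialect. Genes with zero control residual SD (exactly collinear with
#' gestational age) are excluded and logged. When `strata` is supplied (a
#' named column in `meta`, e.g. a <34 / >=34 week split matching case
#' strata), the fit and standardization are done within each stratum.
#'
#' @param m features x samples matrix.
#' @param meta tibble with `sample_id`, `group`, `ga_weeks` (plus the
#'   `strata` column when used).
#' @param degree polynomial degree of the GA regression (default 1).
#' @param strata optional name of a metadata column defining strata.
#' @return Z-score matrix; attribute `dropped_features` lists excluded genes.
#' @export
detrend_crosssectional <- function(m, meta, degree = 1, strata = NULL) {
  stopifnot(is.matrix(m))
  meta <- meta[match(colnames(m), meta$sample_id), ]
  if (!is.null(strata)) {
    lev <- unique(meta[[strata]])
    pieces <- lapply(lev, function(s) {
      sel <- meta[[strata]] == s
      detrend_crosssectional(m[, sel, drop = FALSE], meta[sel, ], degree = degree)
    })
    common <- Reduce(intersect, lapply(pieces, rownames))
    z <- do.call(cbind, lapply(pieces, function(p) p[common, , drop = FALSE]))
    z <- z[, colnames(m)[colnames(m) %in% colnames(z)], drop = FALSE]
    attr(z, "provenance") <- list(step = "detrend_crosssectional",
                                  degree = degree, strata = strata)
    attr(z, "dropped_features") <- setdiff(rownames(m), common)
    return(z)
  }
  ctl <- meta$group == "control"
  ga_ctl <- meta$ga_weeks[ctl]
  if (diff(range(ga_ctl)) <= 2) {
    abort("control gestational ages must span more than 2 weeks.",
          class = "placentrace_config_error")
  }
  X_ctl <- stats::poly(ga_ctl, degree = degree, raw = TRUE)
  X_all <- matrix(rep(meta$ga_weeks, degree), ncol = degree)^
    rep(seq_len(degree), each = nrow(meta))
  fit <- lm.fit(cbind(1, X_ctl), t(m[, ctl, drop = FALSE]))
  coefs <- as.matrix(fit$coefficients)
  resid_all <- m - t(cbind(1, X_all) %*% coefs)
  rsd <- apply(resid_all[, ctl, drop = FALSE], 1, sd)
  keep <- rsd > 1e-12
  if (!all(keep)) {
    inform(paste0(sum(!keep), " feature(s) exactly explained by gestational age; excluded."))
  }
  z <- resid_all[keep, , drop = FALSE] / rsd[keep]
  attr(z, "provenance") <- list(step = "detrend_crosssectional", degree = degree)
  attr(z, "dropped_features") <- rownames(m)[!keep]
  z
}

#' Remove the gestational-age trend by regression-spline GAM, anchored to T1
#'
#' Per protein, fits a smooth gestational-age trend on controls using an
#' unpenalized cubic regression spline with the configured basis dimension
#' (a fixed-degrees-of-freedom GAM fit; deterministic, no smoothing-parameter
#' selection), subtracts the trend from all samples, and standardizes the
#' result to first-window (T1) controls via [anchor_zscore()].
#'
#' @param m features x samples matrix.
#' @param meta tibble with `sample_id`, `group`, `ga_weeks`, `window`.
#' @param basis_dim spline basis dimension; must lie in \[3, 6\].
#' @param anchor_window window label of the anchoring controls (default "T1").
#' @return Z-score matrix (see [anchor_zscore()] for attributes).
#' @export
detrend_gam <- function(m, meta, basis_dim = 4, anchor_window = "T1") {
  stopifnot(is.matrix(m))
  if (basis_dim < 3 || basis_dim > 6) {
    abort("basis_dim must lie in [3, 6].", class = "placentrace_config_error")
  }
  meta <- meta[match(colnames(m), meta$sample_id), ]
  ctl <- meta$group == "control"
  if (diff(range(meta$ga_weeks[ctl])) <= 2) {
    abort("control gestational ages must span more than 2 weeks.",
          class = "placentrace_config_error")
  }
  dat_ctl <- data.frame(ga = meta$ga_weeks[ctl])
  dat_all <- data.frame(ga = meta$ga_weeks)
  out <- m
  for (g in seq_len(nrow(m))) {
    dat_ctl$y <- m[g, ctl]
    fit <- mgcv::gam(y ~ s(ga, k = basis_dim, fx = TRUE, bs = "cr"),
                     data = dat_ctl)
    out[g, ] <- m[g, ] - as.numeric(predict(fit, newdata = dat_all))
  }
  anchors <- meta$sample_id[ctl & meta$window == anchor_window]
  z <- anchor_zscore(out, anchors)
  prov <- attr(z, "provenance")
  prov$step <- "detrend_gam"
  prov$basis_dim <- basis_dim
  attr(z, "provenance") <- prov
  z
}

#' Collapse probes or aptamers to gene level
#'
#' Maps features to gene symbols and keeps, per gene, the single feature
#' maximizing the chosen criterion: coefficient of variation (SD/mean on the
#' matrix values as given; the microarray rule) or variance (the proteomic
#' rule). Features mapping to multiple genes (semicolon-separated
#' `gene_symbols`, e.g. protein complexes) are removed first when
#' `drop_multigene` is set. Ties are broken lexicographically by feature id,
#' so the result does not depend on input order.
#'
#' @param m features x samples matrix (raw or Z-scored).
#' @param map tibble with `feature_id` and `gene_symbols`
#'   (semicolon-separated for multi-gene features).
#' @param method `"max_cv"` or `"max_variance"`.
#' @param drop_multigene drop features mapping to more than one gene.
#' @return genes x samples matrix; attribute `collapse_log` records the
#'   chosen feature per gene.
#' @export
collapse_features <- function(m, map, method = c("max_cv", "max_variance"),
                              drop_multigene = FALSE) {
  stopifnot(is.matrix(m))
  method <- match.arg(method)
  map <- as_tibble(map)
  missing <- setdiff(rownames(m), map$feature_id)
  if (length(missing) > 0) {
    abort(paste0("feature map does not cover: ",
                 paste(utils::head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) ", ..."),
          class = "placentrace_validation_error")
  }
  map <- map |> filter(.data$feature_id %in% rownames(m))
  multi <- grepl(";", map$gene_symbols, fixed = TRUE)
  if (drop_multigene) map <- map[!multi, , drop = FALSE]
  crit <- apply(m, 1, function(x) {
    if (method == "max_cv") sd(x) / mean(x) else var(x)
  })
  long <- map |>
    mutate(gene = strsplit(.data$gene_symbols, ";", fixed = TRUE)) |>
    tidyr::unnest("gene") |>
    mutate(crit = crit[.data$feature_id]) |>
    filter(is.finite(.data$crit)) |>
    arrange(.data$gene, dplyr::desc(.data$crit), .data$feature_id) |>
    group_by(.data$gene) |>
    dplyr::slice(1) |>
    ungroup()
  if (nrow(long) == 0) {
    abort("no genes survive feature collapsing.", class = "placentrace_empty_error")
  }
  out <- m[long$feature_id, , drop = FALSE]
  rownames(out) <- long$gene
  attr(out, "collapse_log") <- long |>
    select("gene", "feature_id", criterion = "crit")
  attr(out, "provenance") <- list(step = "collapse_features", method = method,
                                  drop_multigene = drop_multigene)
  out
}
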