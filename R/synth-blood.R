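#' Configuration for synthetic maternal blood / plasma datasets
#'
#' Shared configuration for [simulate_blood_longitudinal()] (probe-level
#' whole-blood expression with repeated visits per subject) and
#' [simulate_proteomics()] (aptamer-level plasma abundances sampled once per
#' gestational window). The generative model per feature is
#' `value = trend(ga) + subject intercept + noise (+ planted case shift)`,
#' with a quadratic gestational-age trend per gene (recoverable by a
#' degree-2 B-spline) and planted case elevation of signature genes after
#' an onset gestational age.
#'
#' @param n_subjects_control,n_subjects_case subject counts.
#' @param samples_per_subject visits per subject (longitudinal design);
#'   visits are spread evenly over `ga_range` with small jitter, so the first
#'   visit of every subject falls at or before 11 weeks under the default
#'   range and the early-control anchoring set is non-empty.
#' @param ga_range gestational-age range in weeks, within \[5, 42\].
#' @param n_genes_background genes simulated beyond the signature genes.
#' @param trend_sd SD of the random per-gene linear and quadratic trend
#'   coefficients (0 turns trends off).
#' @param subject_sd SD of per-subject random intercepts (drawn independently
#'   per gene, matching the per-gene mixed model fitted downstream).
#' @param noise_sd residual SD.
#' @param planted_shift case elevation of signature-gene features, in Z units
#'   (i.e. in units of `sqrt(subject_sd^2 + noise_sd^2)`; raw units when that
#'   scale is zero). Must be >= 0.
#' @param onset_ga gestational age (weeks) at which the planted shift turns
#'   on in case subjects; defaults to 20, the gestational age after which
#'   preeclampsia is defined.
#' @param planted_signatures names of the signatures whose genes receive the
#'   shift; `NULL` means all signatures passed to the simulator.
#' @param window_defs named list of `c(lo, hi)` gestational windows in weeks;
#'   treated as half-open `[lo, hi)` except the last, which is closed, so the
#'   windows partition their union. Defaults to T1 (15-22), T2 (22-30),
#'   T3 (30-42).
#' @param dup_probe_every every k-th gene receives a second probe/aptamer, so
#'   feature-to-gene collapsing is exercised.
#' @param gene_universe optional explicit gene universe; by default the
#'   universe is the union of the signature genes and the background genes.
#'   When given, every signature gene must be present, otherwise the
#'   simulators raise an error naming the missing gene.
#' @param seed root RNG seed.
#' @return A list of class `blood_sim_config`.
#' @export
blood_sim_config <- function(n_subjects_control = 49,
                             n_subjects_case = 13,
                             samples_per_subject = 5,
                             ga_range = c(8, 41),
                             n_genes_background = 200,
                             trend_sd = 0.5,
                             subject_sd = 0.5,
                             noise_sd = 1,
                             planted_shift = 1,
                             onset_ga = 20,
                             planted_signatures = NULL,
                             window_defs = list(T1 = c(15, 22),
                                                T2 = c(22, 30),
                                                T3 = c(30, 42)),
                             dup_probe_every = 5,
                             gene_universe = NULL,
                             seed = 1L) {
  if (ga_range[1] < 5 || ga_range[2] > 42 || diff(ga_range) <= 0) {
    abort("ga_range must be increasing and within [5, 42] weeks.",
          class = "placentrace_config_error")
  }
  if (planted_shift < 0) {
    abort("planted_shift must be >= 0.", class = "placentrace_config_error")
  }
  w <- do.call(rbind, window_defs)
  if (is.null(rownames(w)) || any(rownames(w) == "")) {
    abort("window_defs must be a named list.", class = "placentrace_config_error")
  }
  o <- order(w[, 1])
  if (any(w[o, 1][-1] < w[o, 2][-nrow(w)])) {
    abort("windows must not overlap.", class = "placentrace_config_error")
  }
  structure(
    list(n_subjects_control = as.integer(n_subjects_control),
         n_subjects_case = as.integer(n_subjects_case),
         samples_per_subject = as.integer(samples_per_subject),
         ga_range = ga_range, n_genes_background = as.integer(n_genes_background),
         trend_sd = trend_sd, subject_sd = subject_sd, noise_sd = noise_sd,
         planted_shift = planted_shift, onset_ga = onset_ga,
         planted_signatures = planted_signatures, window_defs = window_defs,
         dup_probe_every = as.integer(dup_probe_every),
         gene_universe = gene_universe, seed = as.integer(seed)),
    class = "blood_sim_config"
  )
}

#' Assign gestational-age windows
#'
#' Windows are half-open `[lo, hi)` except the last (closed at both ends);
#' samples outside every window get `"none"`.
#'
#' @param ga_weeks numeric vector of gestational ages.
#' @param window_defs named list of `c(lo, hi)` pairs.
#' @return Character vector of window labels.
#' @export
assign_window <- function(ga_weeks,
                          window_defs = list(T1 = c(15, 22), T2 = c(22, 30),
                                             T3 = c(30, 42))) {
  labels <- names(window_defs)
  out <- rep("none", length(ga_weeks))
  last <- length(window_defs)
  for (k in seq_along(window_defs)) {
    lo <- window_defs[[k]][1]; hi <- window_defs[[k]][2]
    hit <- if (k == last) ga_weeks >= lo & ga_weeks <= hi
           else ga_weeks >= lo & ga_weeks < hi
    out[hit] <- labels[k]
  }
  out
}

# gene universe + feature map shared by both circulating-platform simulators
build_feature_universe <- function(cfg, signatures, prefix,
                                   multi_gene = FALSE) {
  sig_genes <- unique(signatures$gene)
  if (is.null(cfg$gene_universe)) {
    background <- sprintf("BG%04d", seq_len(cfg$n_genes_background))
    universe <- union(sig_genes, background)
  } else {
    universe <- cfg$gene_universe
  }
  missing <- setdiff(sig_genes, universe)
  if (length(missing) > 0) {
    abort(paste0("signature gene(s) absent from simulated universe: ",
                 paste(missing, collapse = ", ")),
          class = "placentrace_config_error")
  }
  dup_idx <- seq(1, length(universe), by = max(cfg$dup_probe_every, 2L))
  map <- tibble(
    feature_id = c(sprintf("%s%05d", prefix, seq_along(universe)),
                   sprintf("%s%05d", prefix, length(universe) + seq_along(dup_idx))),
    gene_symbols = c(universe, universe[dup_idx])
  )
  if (multi_gene) {
    map <- bind_rows(map, tibble(
      feature_id = sprintf("%sMULTI1", prefix),
      gene_symbols = paste(universe[1:2], collapse = ";")
    ))
  }
  list(universe = universe, map = map)
}

# value matrix for a set of (feature, sample) draws given per-gene trends
simulate_feature_matrix <- function(cfg, map, universe, meta, sig_genes) {
  n_feat <- nrow(map); n_smp <- nrow(meta)
  ga_mid <- mean(cfg$ga_range); ga_half <- diff(cfg$ga_range) / 2
  u <- (meta$ga_weeks - ga_mid) / ga_half
  a1 <- rnorm(length(universe), 0, cfg$trend_sd)
  a2 <- rnorm(length(universe), 0, cfg$trend_sd)
  names(a1) <- names(a2) <- universe

  scale <- sqrt(cfg$subject_sd^2 + cfg$noise_sd^2)
  shift_raw <- cfg$planted_shift * if (scale > 0) scale else 1

  subjects <- unique(meta$subject_id)
  subj_idx <- match(meta$subject_id, subjects)
  shift_on <- meta$group != "control" & meta$ga_weeks >= cfg$onset_ga

  m <- matrix(NA_real_, n_feat, n_smp,
              dimnames = list(map$feature_id, meta$sample_id))
  first_gene <- vapply(strsplit(map$gene_symbols, ";", fixed = TRUE), `[`, "", 1)
  for (f in seq_len(n_feat)) {
    g <- first_gene[f]
    trend <- a1[[g]] * u + a2[[g]] * u^2
    b <- rnorm(length(subjects), 0, cfg$subject_sd)[subj_idx]
    eps <- rnorm(n_smp, 0, cfg$noise_sd)
    val <- trend + b + eps
    if (g %in% sig_genes) val <- val + shift_raw * shift_on
    m[f, ] <- val
  }
  m
}

#' Simulate a longitudinal maternal whole-blood expression dataset
#'
#' Probe-level intensities over repeated visits per subject, with per-gene
#' quadratic gestational-age trends, per-subject random intercepts, Gaussian
#' noise, and planted case elevation of signature genes after `onset_ga`.
#' Some genes are covered by two probes so probe collapsing is exercised.
#'
#' @param cfg a [blood_sim_config()].
#' @param signatures a [signature_set()]; its genes define the planted-shift
#'   targets (restricted to `cfg$planted_signatures` when set).
#' @return List with `matrix` (features x samples), `meta` (tibble:
#'   sample_id, subject_id, group, ga_weeks, window), `map` (tibble:
#'   feature_id, gene_symbols), and `truth` (planted shift bookkeeping).
#' @export
simulate_blood_longitudinal <- function(cfg, signatures) {
  stopifnot(inherits(cfg, "blood_sim_config"))
  set.seed(substream_seed(cfg$seed, "blood_longitudinal"))
  uni <- build_feature_universe(cfg, signatures, prefix = "PR")

  subj <- tibble(
    subject_id = c(sprintf("C%03d", seq_len(cfg$n_subjects_control)),
                   sprintf("K%03d", seq_len(cfg$n_subjects_case))),
    group = rep(c("control", "case"), c(cfg$n_subjects_control, cfg$n_subjects_case))
  )
  k <- cfg$samples_per_subject
  meta <- subj |>
    tidyr::expand_grid(visit = seq_len(k)) |>
    mutate(
      ga_weeks = pmin(pmax(
        cfg$ga_range[1] + (.data$visit - 1) * diff(cfg$ga_range) / max(k - 1, 1) +
          rnorm(n(), 0, 0.4),
        cfg$ga_range[1]), cfg$ga_range[2]),
      sample_id = sprintf("%s_V%d", .data$subject_id, .data$visit),
      window = assign_window(.data$ga_weeks, cfg$window_defs)
    ) |>
    select("sample_id", "subject_id", "group", "ga_weeks", "window")

  sig_genes <- planted_genes(cfg, signatures)
  m <- simulate_feature_matrix(cfg, uni$map, uni$universe, meta, sig_genes)
  list(matrix = m, meta = meta, map = uni$map,
       truth = list(planted_genes = sig_genes, planted_shift = cfg$planted_shift,
                    onset_ga = cfg$onset_ga,
                    planted_signatures = planted_signature_names(cfg, signatures)))
}

planted_signature_names <- function(cfg, signatures) {
  if (is.null(cfg$planted_signatures)) unique(signatures$signature)
  else intersect(cfg$planted_signatures, unique(signatures$signature))
}

# Genes receiving the planted case shift: genes of the planted signatures,
# excluding genes also claimed by non-planted signatures, so signatures not
# planted stay genuinely null (cell-type signatures routinely share genes).
planted_genes <- function(cfg, signatures) {
  keep <- planted_signature_names(cfg, signatures)
  g <- unique(signatures$gene[signatures$signature %in% keep])
  other <- unique(signatures$gene[!signatures$signature %in% keep])
  setdiff(g, other)
}

#' Simulate a longitudinal maternal plasma proteomics dataset
#'
#' Aptamer-level abundances with one sample per subject per gestational
#' window, smooth gestational-age trends, and per-window planted case shifts
#' (active once gestational age reaches `onset_ga`). The aptamer-to-gene map
#' contains duplicate-gene aptamers and one multi-gene aptamer
#' (`gene_symbols` of the form `"A;B"`) so the exclusion rule is exercised.
#'
#' @inheritParams simulate_blood_longitudinal
#' @return Same shape as [simulate_blood_longitudinal()].
#' @export
simulate_proteomics <- function(cfg, signatures) {
  stopifnot(inherits(cfg, "blood_sim_config"))
  set.seed(substream_seed(cfg$seed, "proteomics"))
  uni <- build_feature_universe(cfg, signatures, prefix = "APT",
                                multi_gene = TRUE)

  subj <- tibble(
    subject_id = c(sprintf("C%03d", seq_len(cfg$n_subjects_control)),
                   sprintf("K%03d", seq_len(cfg$n_subjects_case))),
    group = rep(c("control", "case"), c(cfg$n_subjects_control, cfg$n_subjects_case))
  )
  wins <- cfg$window_defs
  meta <- subj |>
    tidyr::expand_grid(window = names(wins)) |>
    mutate(
      ga_weeks = map_dbl(.data$window, function(w) {
        runif(1, wins[[w]][1], wins[[w]][2] - 1e-6)
      }),
      sample_id = sprintf("%s_%s", .data$subject_id, .data$window)
    ) |>
    select("sample_id", "subject_id", "group", "ga_weeks", "window")

  sig_genes <- planted_genes(cfg, signatures)
  m <- simulate_feature_matrix(cfg, uni$map, uni$universe, meta, sig_genes)
  list(matrix = m, meta = meta, map = uni$map,
       truth = list(planted_genes = sig_genes, planted_shift = cfg$planted_shift,
                    onset_ga = cfg$onset_ga,
                    planted_signatures = planted_signature_names(cfg, signatures)))
}
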