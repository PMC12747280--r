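#' Pipeline configuration
#'
#' Bundles the thresholds and sub-configurations of the end-to-end synthetic
#' pipeline. All randomness flows from the single `seed`: the single-cell
#' and blood simulators receive deterministic substream seeds derived from
#' it. The configuration round-trips losslessly through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param sc named list of overrides for [sim_config()].
#' @param blood named list of overrides for [blood_sim_config()].
#' @param contrasts contrasts to fit (subset of wholePE/EOPE/LOPE/interaction).
#' @param qc_min_genes,qc_max_mito cell QC thresholds (see
#'   [qc_filter_cells()]); the defaults are the standard 200 detected genes
#'   and 25% mitochondrial reads.
#' @param fdr_cut DEG FDR cutoff (default 0.1).
#' @param min_cells,min_samples pseudo-bulk combination filters.
#' @param signature_direction direction of extracted signatures.
#' @param anchor_max_ga anchoring gestational-age bound (weeks, inclusive).
#' @param collapse_method probe-to-gene collapse rule for the blood matrix.
#' @param min_score_genes minimum signature genes required for scoring.
#' @param ga_lo,ga_hi diagnosis window for the ROC analysis.
#' @param planted_signatures signatures whose genes the blood simulator
#'   elevates in cases; `NULL` plants all extracted signatures.
#' @param seed root seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sc = list(), blood = list(),
                            contrasts = "wholePE",
                            qc_min_genes = 200, qc_max_mito = 0.25,
                            fdr_cut = 0.1,
                            min_cells = 20, min_samples = 3,
                            signature_direction = "up",
                            anchor_max_ga = 11,
                            collapse_method = "max_cv",
                            min_score_genes = 3,
                            ga_lo = 32, ga_hi = 34,
                            planted_signatures = NULL,
                            seed = 1L) {
  if (fdr_cut <= 0 || fdr_cut >= 1) {
    abort("fdr_cut must lie in (0, 1).", class = "placentrace_config_error")
  }
  if (!all(contrasts %in% c("wholePE", "EOPE", "LOPE", "interaction"))) {
    abort("unknown contrast.", class = "placentrace_config_error")
  }
  if (ga_lo >= ga_hi || min_cells < 0 || min_samples < 1) {
    abort("thresholds out of range.", class = "placentrace_config_error")
  }
  structure(
    list(sc = sc, blood = blood, contrasts = contrasts,
         qc_min_genes = qc_min_genes, qc_max_mito = qc_max_mito,
         fdr_cut = fdr_cut,
         min_cells = min_cells, min_samples = min_samples,
         signature_direction = signature_direction,
         anchor_max_ga = anchor_max_ga, collapse_method = collapse_method,
         min_score_genes = min_score_genes, ga_lo = ga_lo, ga_hi = ga_hi,
         planted_signatures = planted_signatures, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$sc <- raw$sc %||% list()
  raw$blood <- raw$blood %||% list()
  do.call(pipeline_config, raw)
}

pipeline_stage <- function(name, expr, log) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
          class = "placentrace_pipeline_error")
  })
  log(sprintf("stage=%s elapsed=%.2fs", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the end-to-end synthetic pipeline
#'
#' Simulates a placental single-cell study, applies cell QC, aggregates to
#' pseudo-bulk, fits the requested differential-expression contrasts,
#' extracts cell-type signatures, simulates a longitudinal maternal blood
#' dataset with planted case elevation of the chosen signatures, projects
#' (anchors, detrends, collapses) the blood matrix, scores the signatures,
#' and evaluates diagnosis-window discrimination. Any stage failure halts
#' with the stage name and cause. Rerunning with the same configuration and
#' seed reproduces the report exactly.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir optional directory for artifacts (DEG table TSV, GMT,
#'   score table TSV, report TSV, provenance JSON, log).
#' @param quiet suppress progress messages.
#' @return List: `study`, `de` (deg_table), `signatures`, `scores`,
#'   `report` (the [evaluate_panel()] tibble), `flagged` (signatures whose
#'   AUC CI lower bound exceeds 0.5), `truth` (planted signature names).
#' @export
run_pipeline <- function(cfg, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log_lines <- character(0)
  log <- function(msg) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", msg)
    log_lines <<- c(log_lines, line)
    if (!quiet) inform(line)
  }

  sc_args <- cfg$sc
  sc_args$seed <- substream_seed(cfg$seed, "pipeline_sc")
  study <- pipeline_stage("simulate_sc",
                          simulate_single_cell_study(do.call(sim_config, sc_args)),
                          log)
  study <- pipeline_stage("qc", qc_filter_cells(study,
                                                min_genes = cfg$qc_min_genes,
                                                max_mito_frac = cfg$qc_max_mito),
                          log)
  pb <- pipeline_stage("aggregate", aggregate_pseudobulk(study), log)
  de <- pipeline_stage("de", map_dfr(cfg$contrasts, function(ctr) {
    fit_de(pb, contrast = ctr, min_cells = cfg$min_cells,
           min_samples = cfg$min_samples)
  }), log)
  class(de) <- unique(c("deg_table", class(tibble())))
  sigs <- pipeline_stage("signatures",
                         extract_signatures(de, fdr_cut = cfg$fdr_cut,
                                            direction = cfg$signature_direction),
                         log)

  blood_args <- cfg$blood
  blood_args$seed <- substream_seed(cfg$seed, "pipeline_blood")
  blood_args$planted_signatures <- cfg$planted_signatures
  blood <- pipeline_stage("simulate_blood", {
    simulate_blood_longitudinal(do.call(blood_sim_config, blood_args), sigs)
  }, log)

  z <- pipeline_stage("project", {
    anchors <- early_control_anchors(blood$meta, max_ga = cfg$anchor_max_ga)
    z <- anchor_zscore(blood$matrix, anchors)
    z <- detrend_crosssectional(z, blood$meta)
    collapse_features(z, blood$map, method = cfg$collapse_method)
  }, log)
  scores <- pipeline_stage("score", {
    score_signatures(z, sigs, meta = blood$meta,
                     min_genes = cfg$min_score_genes)
  }, log)
  report <- pipeline_stage("evaluate", {
    evaluate_panel(scores, plan = "roc", ga_lo = cfg$ga_lo, ga_hi = cfg$ga_hi)
  }, log)
  flagged <- report$signature[report$analysis == "roc" & report$discriminates]

  result <- list(study = study, de = de, signatures = sigs, scores = scores,
                 report = report, flagged = flagged,
                 truth = blood$truth$planted_signatures)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(de, file.path(out_dir, "deg_table.tsv"))
    write_gmt(sigs, file.path(out_dir, "signatures.gmt"))
    readr::write_tsv(scores, file.path(out_dir, "scores.tsv"))
    readr::write_tsv(report, file.path(out_dir, "report.tsv"))
    jsonlite::write_json(
      list(package = "placentrace",
           version = as.character(utils::packageVersion("placentrace")),
           seed = cfg$seed, config_hash = rlang::hash(unclass(cfg)),
           flagged = flagged, planted = result$truth),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }
  result
}
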