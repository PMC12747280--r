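#' ROC curve and AUC with DeLong confidence interval
#'
#' The AUC is the Mann-Whitney probability that a case scores above a
#' control, with ties counted half — computed by pair counting over all
#' (case, control) pairs. The direction is fixed (cases are expected to
#' score higher), so an AUC below 0.5 is reported as such, never flipped.
#' The 95% CI uses the DeLong placement-value variance; when either class
#' has fewer than 5 members, a seeded stratified bootstrap (2000 replicates,
#' percentile interval) is used instead.
#'
#' @param scores numeric vector of scores.
#' @param is_case logical vector (TRUE for cases), same length.
#' @param signature,stratum optional labels carried into the result.
#' @param conf_level confidence level (default 0.95).
#' @param boot_seed seed for the bootstrap fallback.
#' @return A `roc_result` list: auc, ci_low, ci_high, se, n_cases,
#'   n_controls, ci_method, signature, stratum, and the ROC curve points.
#' @export
roc_auc <- function(scores, is_case, signature = NA_character_,
                    stratum = NA_character_, conf_level = 0.95,
                    boot_seed = 1L) {
  stopifnot(length(scores) == length(is_case))
  ok <- !is.na(scores) & !is.na(is_case)
  x <- scores[ok & is_case[ok]]
  y <- scores[ok & !is_case[ok]]
  if (length(x) == 0 || length(y) == 0) {
    abort("both classes must be non-empty.", class = "placentrace_empty_error")
  }
  auc <- auc_pairs(x, y)
  zcrit <- qnorm(1 - (1 - conf_level) / 2)
  if (min(length(x), length(y)) >= 5) {
    v10 <- vapply(x, function(xi) auc_pairs(xi, y), 0)
    v01 <- vapply(y, function(yj) auc_pairs(x, yj), 0)
    se <- sqrt(var(v10) / length(x) + var(v01) / length(y))
    ci <- c(max(0, auc - zcrit * se), min(1, auc + zcrit * se))
    method <- "delong"
  } else {
    set.seed(boot_seed)
    reps <- replicate(2000, {
      auc_pairs(sample(x, replace = TRUE), sample(y, replace = TRUE))
    })
    se <- sd(reps)
    ci <- unname(quantile(reps, c((1 - conf_level) / 2,
                                  1 - (1 - conf_level) / 2)))
    method <- "bootstrap"
  }
  thr <- sort(unique(c(-Inf, scores[ok], Inf)), decreasing = TRUE)
  curve <- tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(x >= t), 0),
    fpr = vapply(thr, function(t) mean(y >= t), 0)
  )
  structure(
    list(auc = auc, ci_low = ci[1], ci_high = ci[2], se = se,
         n_cases = length(x), n_controls = length(y), ci_method = method,
         conf_level = conf_level, signature = signature, stratum = stratum,
         curve = curve),
    class = "roc_result"
  )
}

# P(x > y) + 0.5 P(x == y) over all pairs
auc_pairs <- function(x, y) {
  (sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))) /
    (length(x) * length(y))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f [%.3f, %.3f] (%s; %d cases, %d controls)\n",
              x$auc, x$ci_low, x$ci_high, x$ci_method, x$n_cases, x$n_controls))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @export
glance.roc_result <- function(x, ...) {
  tibble(signature = x$signature, stratum = x$stratum, auc = x$auc,
         ci_low = x$ci_low, ci_high = x$ci_high, se = x$se,
         n_cases = x$n_cases, n_controls = x$n_controls,
         ci_method = x$ci_method,
         discriminates = x$ci_low > 0.5)
}

#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot(object$curve, aes(.data$fpr, .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_line() +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("AUC %.2f [%.2f, %.2f]",
                         object$auc, object$ci_low, object$ci_high)) +
    theme_bw()
}

#' Global gestational-age trend test for signature scores
#'
#' Fits a linear mixed-effects model with degree-2 B-spline fixed effects of
#' gestational age and a random intercept per subject, and compares it to
#' the intercept-plus-random-intercept null by a maximum-likelihood
#' likelihood-ratio test with as many degrees of freedom as spline terms —
#' a global test for any change of the score across gestation. A singular
#' random-effect fit triggers a fixed-effects-only refit, flagged in the
#' result.
#'
#' @param scores a `score_table` (one signature) or any data frame with
#'   `score`, `ga_weeks`, `subject_id`.
#' @param spline_degree B-spline degree (default 2).
#' @param grid_n points of the fitted-trend grid returned.
#' @return A `trend_result` list: signature, p_global, chisq, df, flagged,
#'   and `curve` (tibble ga_weeks, fitted).
#' @export
trend_test <- function(scores, spline_degree = 2, grid_n = 50) {
  stopifnot(all(c("score", "ga_weeks", "subject_id") %in% names(scores)))
  sig <- if ("signature" %in% names(scores)) {
    u <- unique(scores$signature)
    if (length(u) > 1) abort("trend_test expects a single signature; filter first.")
    u
  } else NA_character_
  d <- scores[!is.na(scores$score), ]
  if (sd(d$score) == 0) {
    abort("scores have zero variance; trend is degenerate.",
          class = "placentrace_degenerate_error")
  }
  n_subj <- length(unique(d$subject_id))
  if (n_subj < 3) abort("need at least 3 subjects.", class = "placentrace_config_error")
  if (n_subj < 10) warn("fewer than 10 subjects; trend test is underpowered.")
  basis <- ga_spline_basis(d$ga_weeks, spline_degree)
  B <- basis(d$ga_weeks)
  dat <- data.frame(score = d$score, subj = factor(d$subject_id))
  flagged <- FALSE
  full <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(score ~ B + (1 | subj), data = dat, REML = FALSE)
    )), error = function(e) NULL)
  if (is.null(full) || lme4::isSingular(full)) {
    flagged <- TRUE
    full_fe <- lm(score ~ B, data = dat)
    null_fe <- lm(score ~ 1, data = dat)
    chisq <- as.numeric(2 * (logLik(full_fe) - logLik(null_fe)))
    df <- ncol(B)
    fe <- coef(full_fe)
  } else {
    null <- suppressWarnings(suppressMessages(
      lme4::lmer(score ~ 1 + (1 | subj), data = dat, REML = FALSE)))
    lrt <- anova(null, full)
    chisq <- lrt$Chisq[2]
    df <- lrt$Df[2]
    fe <- lme4::fixef(full)
  }
  p <- pchisq(chisq, df = df, lower.tail = FALSE)
  grid <- seq(min(d$ga_weeks), max(d$ga_weeks), length.out = grid_n)
  curve <- tibble(ga_weeks = grid,
                  fitted = as.numeric(cbind(1, basis(grid)) %*% fe))
  structure(list(signature = sig, p_global = p, chisq = chisq, df = df,
                 flagged = flagged, curve = curve),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> %s: LRT chisq %.2f (df %d), p = %.3g%s\n",
              x$signature %||% "score", x$chisq, x$df, x$p_global,
              if (x$flagged) " [no random effect]" else ""))
  invisible(x)
}

#' @export
tidy.trend_result <- function(x, ...) x$curve

#' @export
glance.trend_result <- function(x, ...) {
  tibble(signature = x$signature, p_global = x$p_global, chisq = x$chisq,
         df = x$df, flagged = x$flagged)
}

#' @export
autoplot.trend_result <- function(object, ...) {
  ggplot(object$curve, aes(.data$ga_weeks, .data$fitted)) +
    geom_line(colour = "steelblue") +
    labs(x = "gestational age (weeks)", y = "fitted score trend") +
    theme_bw()
}

#' Select diagnosis-window samples, one per patient
#'
#' Restricts to samples collected between `lo` and `hi` weeks of gestation
#' (inclusive) and keeps exactly one sample per subject — the earliest
#' in-window visit by default.
#'
#' @param meta sample metadata with `sample_id`, `subject_id`, `ga_weeks`.
#' @param lo,hi gestational-age bounds in weeks (default 32-34).
#' @param keep `"earliest"` or `"latest"` in-window visit per subject.
#' @return The selected rows of `meta`.
#' @export
select_diagnosis_samples <- function(meta, lo = 32, hi = 34,
                                     keep = c("earliest", "latest")) {
  keep <- match.arg(keep)
  sel <- meta |> filter(.data$ga_weeks >= lo, .data$ga_weeks <= hi)
  if (nrow(sel) == 0) {
    abort(sprintf("no samples between %g and %g weeks.", lo, hi),
          class = "placentrace_empty_error")
  }
  sel <- sel |> group_by(.data$subject_id)
  sel <- if (keep == "earliest") slice_min(sel, .data$ga_weeks, n = 1,
                                           with_ties = FALSE)
         else slice_max(sel, .data$ga_weeks, n = 1, with_ties = FALSE)
  ungroup(sel)
}

#' Case-control comparison of scores within a gestational window
#'
#' Welch two-sample t-test of signature scores between cases and controls
#' within one gestational-age window (two-sided).
#'
#' @param scores a `score_table` with `group` and `window` columns.
#' @param window window label (e.g. `"T2"`).
#' @return Tibble: window, t, p_value, mean_case, mean_control, n_case,
#'   n_control.
#' @export
window_ttest <- function(scores, window) {
  d <- scores[scores$window == window & !is.na(scores$score), ]
  x <- d$score[d$group != "control"]
  y <- d$score[d$group == "control"]
  if (length(x) == 0 || length(y) == 0) {
    abort(sprintf("window %s is empty for one of the groups.", window),
          class = "placentrace_empty_error")
  }
  tt <- tryCatch(t.test(x, y), error = function(e) {
    abort(sprintf("t-test degenerate in window %s: %s", window,
                  conditionMessage(e)),
          class = "placentrace_degenerate_error")
  })
  tibble(window = window, t = unname(tt$statistic), p_value = tt$p.value,
         mean_case = mean(x), mean_control = mean(y),
         n_case = length(x), n_control = length(y))
}

#' Evaluate a signature panel across platforms
#'
#' Orchestrates the per-signature analyses over one or more platforms'
#' score tables: longitudinal trend tests (fitted on control subjects),
#' diagnosis-window ROC/AUC, and per-window t-tests. A signature
#' "discriminates" when the lower bound of its AUC confidence interval
#' exceeds 0.5.
#'
#' @param scores a `score_table` or a named list of them (one per platform).
#' @param plan subset of `c("roc", "trend", "window")`.
#' @param ga_lo,ga_hi diagnosis window for the ROC analysis.
#' @param windows window labels for the t-tests (default the windows present).
#' @return One tidy tibble: platform, signature, analysis, stratum, auc,
#'   ci_low, ci_high, p_value, mean_case, mean_control, discriminates.
#' @export
evaluate_panel <- function(scores, plan = c("roc", "trend", "window"),
                           ga_lo = 32, ga_hi = 34, windows = NULL) {
  plan <- match.arg(plan, several.ok = TRUE)
  if (!is.data.frame(scores) && !is.list(scores)) {
    abort("scores must be a score_table or a named list of them.")
  }
  if (is.data.frame(scores)) scores <- list(platform1 = scores)
  if (any(vapply(scores, nrow, 0L) == 0)) {
    abort("empty score table supplied.", class = "placentrace_empty_error")
  }
  map_dfr(names(scores), function(pf) {
    tab <- scores[[pf]]
    sig_names <- unique(tab$signature)
    if (length(sig_names) == 0) {
      abort("score table has no signatures.", class = "placentrace_empty_error")
    }
    map_dfr(sig_names, function(nm) {
      st <- tab[tab$signature == nm & !is.na(tab$score), ]
      rows <- list()
      if ("trend" %in% plan) {
        tr <- trend_test(st[st$group == "control", ])
        rows$trend <- tibble(analysis = "trend", stratum = "gestation",
                             p_value = tr$p_global)
      }
      if ("roc" %in% plan) {
        diag <- select_diagnosis_samples(st, lo = ga_lo, hi = ga_hi)
        rr <- roc_auc(diag$score, diag$group != "control", signature = nm,
                      stratum = sprintf("%g-%g weeks", ga_lo, ga_hi))
        rows$roc <- tibble(analysis = "roc", stratum = rr$stratum,
                           auc = rr$auc, ci_low = rr$ci_low,
                           ci_high = rr$ci_high,
                           discriminates = rr$ci_low > 0.5)
      }
      if ("window" %in% plan) {
        wins <- windows %||% setdiff(sort(unique(st$window)), "none")
        rows$window <- map_dfr(wins, function(w) {
          wt <- window_ttest(st, w)
          tibble(analysis = "window", stratum = w, p_value = wt$p_value,
                 mean_case = wt$mean_case, mean_control = wt$mean_control)
        })
      }
      bind_rows(rows) |> mutate(platform = pf, signature = nm)
    })
  }) |>
    select("platform", "signature", "analysis", "stratum",
           dplyr::everything())
}
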