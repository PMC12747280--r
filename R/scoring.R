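#' Per-sample signature scores
#'
#' The score of a signature in a sample is the unweighted mean of the
#' gene-level Z-scores over the signature genes present in the matrix.
#' For signatures containing down-regulated genes, the default is the mean
#' of the up genes minus the mean of the down genes, preserving the
#' convention that scores are higher in cases (set `pure_mean = TRUE` for a
#' plain mean over all genes). Missing values within a retained gene are
#' dropped per sample (pairwise deletion), and the genes actually used are
#' reported. Signatures with fewer than `min_genes` genes on the platform
#' are flagged (score `NA`).
#'
#' @param z gene-level Z matrix (genes x samples; post-collapse).
#' @param sigs a [signature_set()].
#' @param meta optional sample metadata joined onto the result by
#'   `sample_id`.
#' @param min_genes minimum signature genes required on the platform.
#' @param pure_mean ignore per-gene directions and average all genes.
#' @return A `score_table` tibble: sample_id, signature, score,
#'   n_genes_used, coverage_fraction (n_genes_used / signature size), plus
#'   metadata columns when supplied.
#' @export
score_signatures <- function(z, sigs, meta = NULL, min_genes = 3,
                             pure_mean = FALSE) {
  stopifnot(is.matrix(z))
  sigs <- validate_signature_set(as_tibble(sigs))
  sig_names <- unique(sigs$signature)
  any_overlap <- FALSE
  out <- map_dfr(sig_names, function(nm) {
    sg <- sigs[sigs$signature == nm, ]
    present <- sg[sg$gene %in% rownames(z), ]
    size <- nrow(sg)
    if (nrow(present) > 0) any_overlap <<- TRUE
    if (nrow(present) < min_genes) {
      return(tibble(sample_id = colnames(z), signature = nm,
                    score = NA_real_, n_genes_used = 0L,
                    coverage_fraction = nrow(present) / size))
    }
    sign_vec <- ifelse(present$direction == "down" & !pure_mean, -1, 1)
    up <- present$gene[sign_vec > 0]
    dn <- present$gene[sign_vec < 0]
    col_mean <- function(gset) {
      if (length(gset) == 0) return(rep(0, ncol(z)))
      colMeans(z[gset, , drop = FALSE], na.rm = TRUE)
    }
    score <- col_mean(up) - col_mean(dn)
    n_used <- colSums(!is.na(z[present$gene, , drop = FALSE]))
    score[n_used == 0] <- NA_real_
    tibble(sample_id = colnames(z), signature = nm, score = unname(score),
           n_genes_used = as.integer(unname(n_used)),
           coverage_fraction = nrow(present) / size)
  })
  if (!any_overlap) {
    abort("no signature shares any gene with the matrix.",
          class = "placentrace_empty_error")
  }
  if (!is.null(meta)) {
    out <- left_join(out, as_tibble(meta), by = "sample_id")
  }
  class(out) <- unique(c("score_table", class(tibble())))
  out
}

#' @rdname score_signatures
#' @param x a `score_table` with `group` and `ga_weeks` metadata.
#' @param ... unused.
#' @export
autoplot.score_table <- function(x, ...) {
  stopifnot(all(c("group", "ga_weeks") %in% names(x)))
  ggplot(as_tibble(x),
         aes(.data$ga_weeks, .data$score, colour = .data$group)) +
    geom_point(alpha = 0.5, size = 0.8) +
    facet_wrap(~signature, scales = "free_y") +
    labs(x = "gestational age (weeks)", y = "signature score (Z)") +
    theme_bw()
}
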