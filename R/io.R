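#' Read and write a cell study as MTX plus TSV sidecars
#'
#' The on-disk layout is 10x-style: `matrix.mtx` (sparse genes x cells
#' counts), `genes.tsv` (one gene id per line), `cells.tsv` (barcode,
#' cell_type, sample, group, library, origin), and `samples.tsv` (sample,
#' group, onset, ga_weeks, subject, library). Reading validates dimensions,
#' sample references, and count integrality, and names the offending file in
#' its error messages.
#'
#' @param dir directory holding the four files.
#' @return A `cell_study`.
#' @export
read_mtx_study <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "cells.tsv", "samples.tsv"))
  names(paths) <- basename(paths)
  for (p in paths) {
    if (!file.exists(p)) {
      abort(paste0("missing input file: ", p), class = "placentrace_io_error")
    }
  }
  # readMM warns on truncated files; the explicit header check below turns
  # any entry-count discrepancy into a structured error
  counts <- tryCatch(as(suppressWarnings(readMM(paths[["matrix.mtx"]])),
                        "CsparseMatrix"),
                     error = function(e) {
                       abort(paste0("matrix.mtx is malformed: ",
                                    conditionMessage(e)),
                             class = "placentrace_io_error")
                     })
  # the header's declared entry count must match the entries present
  hdr <- readLines(paths[["matrix.mtx"]], n = 50)
  hdr <- hdr[!grepl("^%", hdr)][1]
  nnz_declared <- as.numeric(strsplit(trimws(hdr), "\\s+")[[1]][3])
  if (!is.na(nnz_declared) && nnz_declared != length(counts@x)) {
    abort(sprintf(
      "matrix.mtx header declares %d entries but %d were read.",
      nnz_declared, length(counts@x)), class = "placentrace_io_error")
  }
  genes <- readr::read_tsv(paths[["genes.tsv"]], col_names = "gene",
                           show_col_types = FALSE)$gene
  cells <- readr::read_tsv(paths[["cells.tsv"]], show_col_types = FALSE)
  samples <- readr::read_tsv(paths[["samples.tsv"]], show_col_types = FALSE)
  if (nrow(counts) != length(genes)) {
    abort("genes.tsv length does not match matrix.mtx row count.",
          class = "placentrace_io_error")
  }
  if (ncol(counts) != nrow(cells)) {
    abort("cells.tsv row count does not match matrix.mtx column count.",
          class = "placentrace_io_error")
  }
  bad <- setdiff(unique(cells$sample), samples$sample)
  if (length(bad) > 0) {
    first <- cells$barcode[cells$sample %in% bad][1]
    abort(paste0("cells.tsv references unknown sample(s) (e.g. barcode ",
                 first, " -> ", bad[1], ")."),
          class = "placentrace_io_error")
  }
  if (any(counts@x != round(counts@x)) || any(counts@x < 0)) {
    abort("matrix.mtx contains non-integer or negative counts.",
          class = "placentrace_io_error")
  }
  dimnames(counts) <- list(genes, cells$barcode)
  new_cell_study(counts, cells, samples)
}

#' @rdname read_mtx_study
#' @param study a `cell_study`.
#' @export
write_mtx_study <- function(study, dir) {
  stopifnot(inherits(study, "cell_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeMM(study$counts, file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble(gene = rownames(study$counts)),
                   file.path(dir, "genes.tsv"), col_names = FALSE)
  readr::write_tsv(study$cells, file.path(dir, "cells.tsv"))
  readr::write_tsv(study$samples, file.path(dir, "samples.tsv"))
  invisible(dir)
}

#' Read and write signature sets as GMT
#'
#' One line per (signature, direction) block: signature name, a description
#' field `source=<contrast>;direction=<up|down>`, then tab-separated genes.
#' Signatures holding both up and down genes span two lines with the same
#' name and are merged on read, so the round trip is lossless. Malformed
#' lines, duplicate genes within a block, and empty gene lists are rejected
#' with the line number.
#'
#' @param path GMT file path.
#' @return A [signature_set()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sigs <- map_dfr(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(paste0("malformed GMT line ", i, ": fewer than 3 fields."),
            class = "placentrace_io_error")
    }
    desc <- f[2]
    src <- sub("^.*source=([^;]+).*$", "\\1", desc)
    dir <- if (grepl("direction=", desc)) {
      sub("^.*direction=([^;]+).*$", "\\1", desc)
    } else "up"
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      abort(paste0("GMT line ", i, ": empty gene list."),
            class = "placentrace_io_error")
    }
    if (anyDuplicated(genes)) {
      abort(paste0("GMT line ", i, ": duplicate gene(s) within the set."),
            class = "placentrace_io_error")
    }
    tibble(signature = f[1], source = src, direction = dir, gene = genes)
  })
  validate_signature_set(sigs)
}

#' @rdname read_gmt
#' @param sigs a [signature_set()].
#' @export
write_gmt <- function(sigs, path) {
  sigs <- validate_signature_set(as_tibble(sigs))
  blocks <- sigs |>
    group_by(.data$signature, .data$source, .data$direction) |>
    summarise(genes = paste(.data$gene, collapse = "\t"), .groups = "drop")
  lines <- sprintf("%s\tsource=%s;direction=%s\t%s",
                   blocks$signature, blocks$source, blocks$direction,
                   blocks$genes)
  writeLines(lines, path)
  invisible(path)
}

#' Read/write feature x sample matrices as TSV
#'
#' First column `feature_id`, remaining columns one per sample.
#'
#' @param m numeric matrix with dimnames.
#' @param path TSV path.
#' @return `read_matrix_tsv` returns the matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- bind_cols(tibble(feature_id = rownames(m)),
                  as_tibble(as.data.frame(m)))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}
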