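#' Build a signature set
#'
#' A signature set is a tibble with one row per (signature, gene) pair and
#' columns `signature`, `source` (the contrast the signature was derived
#' from: wholePE, EOPE or LOPE), `direction` (`"up"` or `"down"`, per gene),
#' and `gene`. Scores are computed so that up-regulated genes raise and
#' down-regulated genes lower the score, preserving the convention that
#' scores are higher in preeclampsia cases.
#'
#' @param genes named list of character vectors (names become signature
#'   names), or a tibble already in long form.
#' @param source source contrast label, recycled.
#' @param direction per-signature direction, recycled (`"up"`, `"down"`).
#' @return A tibble of class `signature_set`.
#' @export
signature_set <- function(genes, source = "wholePE", direction = "up") {
  if (is.data.frame(genes)) {
    sigs <- as_tibble(genes)
    if (!all(c("signature", "gene") %in% names(sigs))) {
      abort("signature data frame needs columns `signature` and `gene`.")
    }
    if (!"source" %in% names(sigs)) sigs$source <- source
    if (!"direction" %in% names(sigs)) sigs$direction <- direction
  } else {
    sigs <- imap(genes, function(g, nm) {
      tibble(signature = nm, gene = as.character(g))
    }) |> bind_rows()
    sigs$source <- rep(source, length.out = nrow(sigs))
    sigs$direction <- rep(direction, length.out = nrow(sigs))
  }
  validate_signature_set(sigs)
}

validate_signature_set <- function(sigs) {
  if (nrow(sigs) == 0) abort("signature set is empty.", class = "placentrace_validation_error")
  dup <- sigs |> count(.data$signature, .data$gene) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate gene(s) within a signature: ",
                 paste(unique(dup$gene), collapse = ", ")),
          class = "placentrace_validation_error")
  }
  if (any(is.na(sigs$gene)) || any(sigs$gene == "")) {
    abort("signatures contain empty gene symbols.", class = "placentrace_validation_error")
  }
  if (!all(sigs$direction %in% c("up", "down"))) {
    abort("per-gene direction must be 'up' or 'down'.", class = "placentrace_validation_error")
  }
  class(sigs) <- unique(c("signature_set", class(tibble())))
  sigs[, c("signature", "source", "direction", "gene")]
}

#' @export
print.signature_set <- function(x, ...) {
  cat("<signature_set> ", length(unique(x$signature)), " signature(s), ",
      nrow(x), " genes\n", sep = "")
  NextMethod()
}
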