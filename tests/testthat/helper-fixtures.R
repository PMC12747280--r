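# Hand-built fixtures used across test files. Everything is constructed in
# code; no data files.

# A tiny cell study with fully known counts: 2 cell types, 4 samples
# (2 control / 2 case), counts chosen by hand.
toy_study <- function() {
  genes <- c("MT-1", "GA", "GB", "GC")
  barcodes <- sprintf("b%02d", 1:8)
  counts <- matrix(
    c( # one column per cell (genes in rows: MT-1, GA, GB, GC)
      0, 1, 0, 2,   # b01 typeA S1
      0, 2, 3, 0,   # b02 typeA S1
      1, 0, 1, 1,   # b03 typeA S2
      0, 4, 0, 0,   # b04 typeB S2
      2, 1, 1, 0,   # b05 typeB S3
      0, 0, 2, 2,   # b06 typeB S3
      1, 1, 0, 1,   # b07 typeA S4
      0, 3, 1, 0),  # b08 typeB S4
    nrow = 4, dimnames = list(genes, barcodes))
  cells <- tibble::tibble(
    barcode = barcodes,
    cell_type = c("typeA", "typeA", "typeA", "typeB",
                  "typeB", "typeB", "typeA", "typeB"),
    sample = c("S1", "S1", "S2", "S2", "S3", "S3", "S4", "S4"),
    group = c("control", "control", "control", "control",
              "EOPE", "EOPE", "EOPE", "EOPE"),
    library = "L01",
    origin = "maternal")
  samples <- tibble::tibble(
    sample = c("S1", "S2", "S3", "S4"),
    group = c("control", "control", "EOPE", "EOPE"),
    onset = "EOPE",
    ga_weeks = c(30, 31, 30.5, 31.5),
    subject = paste0("P", 1:4),
    library = "L01")
  cell_study(counts, cells, samples)
}

# Small simulated study shared by several DE tests.
small_sim_study <- function(seed = 3, frac_de = 0.05, log2fc = 2, prop_up = 1,
                            n_genes = 600, n_per_group = 8) {
  cfg <- sim_config(
    n_genes = n_genes, n_cell_types = 3, n_samples_per_group = n_per_group,
    cells_per_type = list(mean = 100, dispersion = 0.3),
    frac_de = frac_de, log2fc_de = log2fc, prop_up = prop_up, seed = seed)
  simulate_single_cell_study(cfg)
}

# Brute-force AUC by explicit pair enumeration (independent oracle).
auc_brute <- function(cases, controls) {
  tot <- 0
  for (x in cases) for (y in controls) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(cases) * length(controls))
}

# Brute-force Benjamini-Hochberg step-up (independent oracle).
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

sig_fixture <- function() {
  signature_set(list(SIG_A = sprintf("BG%04d", 1:10),
                     SIG_B = sprintf("BG%04d", 11:25)),
                source = "EOPE")
}
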