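# Shared study-condition builders for the test suite.

# A pair whose two references are identical (ancestry-matched mapping):
# the seven separating substitutions are present in both panels.
matched_ighg_spec <- function() {
  pos <- c(215L, 225L, 235L, 245L, 255L, 265L, 285L)
  pair_spec("IGHG1/IGHG2", "IGHG1", "IGHG2",
            variants = data.frame(ref = rep(c("refA", "refB"), each = 7),
                                  pos = rep(pos, 2), carrier = "gene1"))
}

# Wrap a dense named matrix as a CountMatrix.
toy_cm <- function(m) {
  feats <- rownames(m)
  structure(list(
    counts = methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
    features = data.frame(
      feature_id = feats, is_mito = grepl("^MT-", feats),
      is_ribo = grepl("^RP[LS]", feats), is_ig = grepl("^IG[HKL]", feats),
      is_isotype = grepl("^IGH[MDEGA]", feats), stringsAsFactors = FALSE),
    barcodes = colnames(m),
    tallies = data.frame(class = c("effective", "pcr_duplicate",
                                   "discarded_multimap", "unmapped"),
                         n = c(sum(m), 0L, 0L, 0L)),
    n_nonwhitelist = 0L), class = "CountMatrix")
}

# A small two-pair panel (IgG swap + IgA shared tail) and donor reads.
two_pair_fixture <- function(n_cells = 800, error_rate = 0,
                             pcr_duplication_mean = 1, seed = 7) {
  panels <- build_allele_panel(list(ighg_swap_spec(),
                                    igha_shared_tail_spec()), seed = seed)
  cells <- simulate_cells(n_cells,
                          c(IGHG1 = .25, IGHG2 = .25,
                            IGHA1 = .25, IGHA2 = .25),
                          doublet_rate = 0.02, seed = seed + 1)
  reads <- simulate_reads(panels$refB, cells, error_rate = error_rate,
                          pcr_duplication_mean = pcr_duplication_mean,
                          seed = seed + 2)
  list(panels = panels, cells = cells, reads = reads)
}
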