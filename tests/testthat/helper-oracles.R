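# Independent oracles: deliberately naive re-implementations used only to
# check the package's optimised code paths.

# Cost-only global alignment DP (match 0, mismatch 1, gap 1).
oracle_nw_cost <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0L, n + 1, m + 1)
  M[, 1] <- 0:n
  M[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m))
    M[i + 1, j + 1] <- min(M[i, j] + (a[i] != b[j]),
                           M[i, j + 1] + 1L, M[i + 1, j] + 1L)
  M[n + 1, m + 1]
}

# Best ungapped placement per region via Biostrings (independent of the
# package's compiled scan).
oracle_scan <- function(read, region_seqs, max_mismatch) {
  R <- nchar(read)
  lapply(region_seqs, function(s) {
    n_off <- nchar(s) - R + 1
    if (n_off < 1) return(NULL)
    mm <- Biostrings::neditStartingAt(Biostrings::DNAString(read),
                                      Biostrings::DNAString(s),
                                      starting.at = seq_len(n_off),
                                      with.indels = FALSE)
    keep <- mm <= max_mismatch
    if (!any(keep)) return(NULL)
    best <- min(mm[keep])
    list(best = best, offset = which(mm == best)[1],
         n_best = sum(mm == best))
  })
}

# Classify one read against labelled regions the slow way.
oracle_assign <- function(read, regions, max_mismatch, rescue = TRUE) {
  sc <- oracle_scan(read, regions$seq, max_mismatch)
  ok <- !vapply(sc, is.null, TRUE)
  if (!any(ok)) return(list(class = "unmapped", gene = NA))
  best <- min(vapply(sc[ok], `[[`, 0, "best"))
  at <- which(ok)[vapply(sc[ok], `[[`, 0, "best") == best]
  lab <- vapply(at, function(i) {
    o <- sc[[i]]$offset
    if (!is.na(regions$split_at[i]) && o >= regions$split_at[i])
      regions$shared_gene[i] else regions$gene_id[i]
  }, "")
  n_place <- sum(vapply(sc[at], `[[`, 0, "n_best"))
  if (length(unique(lab)) > 1 || (!rescue && n_place > 1))
    return(list(class = "discarded_multimap", gene = NA))
  list(class = "effective", gene = lab[1], mismatches = best)
}

# Exhaustive window-identity scan for the region decomposition.
oracle_ambiguity <- function(s1, s2, R) {
  n <- nchar(s1) - R + 1
  vapply(seq_len(n), function(o)
    substr(s1, o, o + R - 1) == substr(s2, o, o + R - 1), TRUE)
}

# The four QC rules, re-applied from scratch on a dense matrix.
oracle_qc <- function(m, is_mito, is_ribo, params) {
  keep_cell <- colSums(m[is_mito, , drop = FALSE]) /
    pmax(colSums(m), 1) <= params$max_mito_fraction | colSums(m) == 0
  m <- m[, keep_cell, drop = FALSE]
  m <- m[!is_ribo, , drop = FALSE]
  prev <- rowSums(m > 0) / max(1, ncol(m))
  m <- m[prev >= params$min_gene_prevalence, , drop = FALSE]
  m[, colSums(m) >= params$min_reads & colSums(m > 0) >= params$min_genes,
    drop = FALSE]
}
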