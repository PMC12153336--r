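## Paralog and cross-reference sequence divergence ------------------------

#' Globally align two exon sequences
#'
#' Minimum-cost global alignment with unit mismatch and linear unit gap
#' costs (match 0, mismatch 1, gap 1).  Traceback ties are broken
#' deterministically: diagonal, then up, then left.  Equal-length sequences
#' take a gapless fast path (the paralogous CH3-CHS exons compared here are
#' near-isometric); the dynamic program is used otherwise.
#'
#' @param seqA,seqB Non-empty DNA sequences (character scalars).
#' @return A `pair_alignment`: list with `cost`, gapped strings `aligned_a`
#'   and `aligned_b`, and a per-column data frame `columns` with 1-based
#'   source positions (`NA` at gaps) and a `type` of `"match"`,
#'   `"mismatch"` or `"gap"`.
#' @export
align_pair <- function(seqA, seqB) {
  if (!nzchar(seqA) || !nzchar(seqB)) stop("empty input sequence")
  if (nchar(seqA) == nchar(seqB)) {
    a <- seq_chars(seqA); b <- seq_chars(seqB)
    al <- list(cost = sum(a != b), aligned_a = seqA, aligned_b = seqB)
  } else {
    al <- nw_align_cpp(seqA, seqB)
  }
  ga <- seq_chars(al$aligned_a); gb <- seq_chars(al$aligned_b)
  posA <- cumsum(ga != "-"); posA[ga == "-"] <- NA
  posB <- cumsum(gb != "-"); posB[gb == "-"] <- NA
  type <- ifelse(ga == "-" | gb == "-", "gap",
                 ifelse(ga == gb, "match", "mismatch"))
  structure(list(cost = al$cost, aligned_a = al$aligned_a,
                 aligned_b = al$aligned_b,
                 columns = data.frame(column = seq_along(ga), posA = posA,
                                      posB = posB, baseA = ga, baseB = gb,
                                      type = type)),
            class = "pair_alignment")
}

#' Enumerate variant positions between two aligned sequences
#'
#' One row per mismatch column of the [align_pair()] alignment; gap columns
#' are tallied separately as indels and excluded from `total_variants`.
#' When `coding_end` is given (transcript coordinate of the last coding
#' base, from the annotation's stop-codon boundary) each variant is
#' attributed to the `"coding"` or `"UTR"` compartment.
#'
#' @param seqA,seqB Sequences, or pass a ready `alignment`.
#' @param alignment Optional `pair_alignment` (overrides `seqA`/`seqB`).
#' @param coding_end Optional coding-compartment boundary in `seqA`
#'   coordinates.
#' @return A `VariantTable` data frame (`pos` = alignment column, `posA`,
#'   `posB`, `base_left`, `base_right`, `compartment`) with attributes
#'   `total_variants` and `n_indels`.
#' @export
enumerate_variants <- function(seqA = NULL, seqB = NULL, alignment = NULL,
                               coding_end = NULL) {
  if (is.null(alignment)) alignment <- align_pair(seqA, seqB)
  cols <- alignment$columns
  mm <- cols[cols$type == "mismatch", , drop = FALSE]
  vt <- data.frame(pos = mm$column, posA = mm$posA, posB = mm$posB,
                   base_left = mm$baseA, base_right = mm$baseB,
                   compartment = rep(NA_character_, nrow(mm)),
                   row.names = NULL)
  if (!is.null(coding_end) && nrow(vt))
    vt$compartment <- ifelse(vt$posA <= coding_end, "coding", "UTR")
  structure(vt, total_variants = nrow(vt),
            n_indels = sum(cols$type == "gap"), class = c("VariantTable",
                                                          "data.frame"))
}

#' Decompose a paralog pair's terminal exon into ambiguity regions
#'
#' For every valid read start offset, a reference is "ambiguous" iff the two
#' paralogs' length-`read_length` subsequences starting there are identical
#' in that reference.  Offsets are classified into four classes, with
#' reference A in the role of the ancestry-mismatched (hg38-like)
#' reference: *blue* = ambiguous in B
#' only, *orange* = ambiguous in A only, *red* = distinguishable in both.
#'
#' @param panels Named list of two `AllelePanel`s (A first, B second).
#' @param pair Character vector of the two gene ids, or a declared pair id.
#' @param read_length Read length R (<= exon length).
#' @return A `RegionDecomposition`: list with `read_length`, per-offset data
#'   frame `offsets` (`offset`, `ambiguous_A`, `ambiguous_B`, `class`,
#'   `colour`) and run-length `intervals` (1-based closed, non-overlapping,
#'   sorted, tiling all valid offsets).
#' @export
decompose_regions <- function(panels, pair, read_length) {
  stopifnot(length(panels) == 2L)
  if (length(pair) == 1L) {
    pr <- panels[[1L]]$pairs[[pair]]
    if (is.null(pr)) stop("pair '", pair, "' not declared in panel")
    pair <- pr
  }
  amb <- lapply(panels, function(p) {
    s1 <- terminal_exon_seq(p, pair[1L])
    s2 <- terminal_exon_seq(p, pair[2L])
    window_ambiguity(s1, s2, read_length)
  })
  n <- length(amb[[1L]])
  if (n != length(amb[[2L]]))
    stop("references disagree on the number of valid offsets; ",
         "region decomposition requires a common offset frame")
  a <- amb[[1L]]; b <- amb[[2L]]
  class <- ifelse(a & b, "ambiguous_both",
                  ifelse(a, "ambiguous_A_only",
                         ifelse(b, "ambiguous_B_only", "distinct_both")))
  colour <- c(ambiguous_both = "grey", ambiguous_A_only = "orange",
              ambiguous_B_only = "blue", distinct_both = "red")[class]
  off <- data.frame(offset = seq_len(n), ambiguous_A = a, ambiguous_B = b,
                    class = class, colour = unname(colour))
  r <- rle(class)
  ends <- cumsum(r$lengths)
  intervals <- data.frame(start = ends - r$lengths + 1L, end = ends,
                          class = r$values,
                          colour = unname(colour[match(r$values, class)]))
  structure(list(read_length = read_length, pair = pair, offsets = off,
                 intervals = intervals), class = "RegionDecomposition")
}

## TRUE at offset o iff the two length-R windows starting at o are identical.
## Unequal-length paralogs are projected through the pairwise alignment;
## windows running into a gap or off either end count as distinguishable.
window_ambiguity <- function(s1, s2, R) {
  n1 <- nchar(s1); n2 <- nchar(s2)
  if (R > n1 || R > n2) stop("read_length exceeds exon length")
  if (n1 == n2) {
    starts <- seq_len(n1 - R + 1L)
    w1 <- substring(s1, starts, starts + R - 1L)
    w2 <- substring(s2, starts, starts + R - 1L)
    return(w1 == w2)
  }
  al <- align_pair(s1, s2)
  cols <- al$columns
  map12 <- rep(NA_integer_, n1)
  ok <- !is.na(cols$posA) & !is.na(cols$posB)
  map12[cols$posA[ok]] <- cols$posB[ok]
  starts <- seq_len(n1 - R + 1L)
  vapply(starts, function(o) {
    p2 <- map12[o]
    if (is.na(p2) || p2 + R - 1L > n2) return(FALSE)
    substr(s1, o, o + R - 1L) == substr(s2, p2, p2 + R - 1L)
  }, logical(1L))
}

#' @export
print.RegionDecomposition <- function(x, ...) {
  cat("RegionDecomposition (", x$pair[1L], " vs ", x$pair[2L], ", R = ",
      x$read_length, ")\n", sep = "")
  print(x$intervals)
  invisible(x)
}

#' Compare one gene's alleles across two references
#'
#' Cross-reference [enumerate_variants()] for every copy of `gene` in each
#' panel (duplicated genes produce one comparison per copy pair, flagged).
#'
#' @param panelA,panelB `AllelePanel`s.
#' @param gene Gene symbol.
#' @return Data frame with one row per copy-pair comparison: copy ids, the
#'   coding / UTR / total variant counts, indels, and a `duplicated` flag.
#'   The per-comparison `VariantTable`s are attached as attribute `tables`.
#' @export
compare_references <- function(panelA, panelB, gene) {
  copies_of <- function(p) Filter(function(g) g$symbol == gene, p$genes)
  ca <- copies_of(panelA); cb <- copies_of(panelB)
  if (!length(ca) || !length(cb))
    stop("gene '", gene, "' missing from ",
         if (!length(ca)) panelA$reference_name else panelB$reference_name)
  rows <- list(); tables <- list()
  for (ga in ca) for (gb in cb) {
    sa <- ga$exons[[ga$terminal_exon]]
    sb <- gb$exons[[gb$terminal_exon]]
    vt <- enumerate_variants(sa, sb, coding_end = ga$coding_end)
    key <- paste0(ga$gene_id, "|", gb$gene_id)
    tables[[key]] <- vt
    rows[[key]] <- data.frame(
      symbol = gene, copy_A = ga$gene_id, copy_B = gb$gene_id,
      n_coding = sum(vt$compartment == "coding"),
      n_utr = sum(vt$compartment == "UTR"),
      total_variants = attr(vt, "total_variants"),
      n_indels = attr(vt, "n_indels"),
      duplicated = length(ca) > 1L || length(cb) > 1L)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "tables") <- tables
  out
}

#' Union count of variant columns across a gene family
#'
#' Counts distinct terminal-exon positions at which any family member
#' differs from a chosen anchor gene within one reference -- the
#' union-of-pairwise-variant-columns summary used to compare how
#' distinguishable a subclass family is under alternative references.
#'
#' @param panel An `AllelePanel`.
#' @param genes Gene ids (equal-length terminal exons).
#' @param anchor Anchor gene id (default: first of `genes`).
#' @return Integer count of variant columns.
#' @export
variant_union_count <- function(panel, genes, anchor = genes[1L]) {
  sa <- seq_chars(terminal_exon_seq(panel, anchor))
  pos <- integer(0)
  for (g in setdiff(genes, anchor)) {
    sg <- seq_chars(terminal_exon_seq(panel, g))
    if (length(sg) != length(sa))
      stop("variant_union_count requires equal-length exons")
    pos <- union(pos, which(sg != sa))
  }
  length(pos)
}

#' Write a variant table as TSV
#' @param vt A `VariantTable`.
#' @param file Output path.
#' @export
write_variant_table <- function(vt, file) {
  write.table(as.data.frame(vt), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Write a region decomposition as TSV and BED
#'
#' The TSV holds the per-offset classification; the BED (0-based,
#' half-open, name = class label) holds the run-length intervals.
#'
#' @param dec A `RegionDecomposition`.
#' @param tsv,bed Output paths (either may be `NULL` to skip).
#' @param chrom Chromosome/sequence name for the BED records.
#' @export
write_region_decomposition <- function(dec, tsv = NULL, bed = NULL,
                                       chrom = dec$pair[1L]) {
  if (!is.null(tsv))
    write.table(dec$offsets, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(bed)) {
    iv <- dec$intervals
    bedd <- data.frame(chrom = chrom, start = iv$start - 1L, end = iv$end,
                       name = iv$class)
    write.table(bedd, bed, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(dec)
}
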