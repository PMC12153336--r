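## Synthetic cell populations and 3' reads --------------------------------

#' Simulate a plasma-cell population with ground truth
#'
#' Each cell carries one true isotype ("one cell, one antibody"); doublets
#' (two cells under one barcode) are drawn independently at `doublet_rate`,
#' carry a second, different isotype, and have a library size that is the
#' sum of two independent log-normal draws -- so doublets are stochastically
#' about twice as deep as singlets, the signal exploited by the library-size
#' doublet diagnostic.
#'
#' @param n_cells Number of barcodes (> 0).
#' @param isotype_proportions Named probability vector over isotype gene ids
#'   (must sum to 1 within 1e-9).
#' @param doublet_rate Doublet probability in [0, 0.5].
#' @param libsize_log_mean,libsize_log_sd Log-normal parameters of the
#'   per-cell molecule count (library size before PCR duplication).
#' @param mito_shape1,mito_shape2 Beta parameters of the per-cell
#'   mitochondrial fraction (default mean 5\%).
#' @param background_fraction Fraction of each cell's transcriptome carried
#'   by non-immunoglobulin background genes (scalar, in [0, 1)).
#' @param seed Integer seed.
#' @return A `CellTruthTable` data frame: `barcode` (unique 16-mers),
#'   `true_isotype`, `is_doublet`, `second_isotype` (`NA` for singlets),
#'   `library_size`, `library_size_second` (the doublet partner's share),
#'   `mito_fraction`, `background_fraction`.
#' @export
simulate_cells <- function(n_cells, isotype_proportions, doublet_rate = 0.02,
                           libsize_log_mean = log(80), libsize_log_sd = 0.5,
                           mito_shape1 = 2, mito_shape2 = 38,
                           background_fraction = 0.4, seed = 1L) {
  if (n_cells == 0L) stop("n_cells must be positive (empty table)")
  p <- isotype_proportions
  if (is.null(names(p)) || abs(sum(p) - 1) > 1e-9)
    stop("isotype_proportions must be named and sum to 1")
  if (doublet_rate < 0 || doublet_rate > 0.5)
    stop("doublet_rate must be in [0, 0.5]")
  set.seed(seed)
  barcode <- random_dna(n_cells, 16L)
  while (anyDuplicated(barcode)) {  # negligible at 16-mers, but keep unique
    dup <- duplicated(barcode)
    barcode[dup] <- random_dna(sum(dup), 16L)
  }
  genes <- names(p)
  true_iso <- sample(genes, n_cells, replace = TRUE, prob = p)
  is_doublet <- runif(n_cells) < doublet_rate
  second <- rep(NA_character_, n_cells)
  if (any(is_doublet)) {
    second[is_doublet] <- vapply(true_iso[is_doublet], function(g) {
      q <- p[setdiff(genes, g)]
      sample(names(q), 1L, prob = q / sum(q))
    }, "")
  }
  ls1 <- pmax(1L, as.integer(round(rlnorm(n_cells, libsize_log_mean,
                                          libsize_log_sd))))
  ls2 <- rep(0L, n_cells)
  ls2[is_doublet] <- pmax(1L, as.integer(round(
    rlnorm(sum(is_doublet), libsize_log_mean, libsize_log_sd))))
  mito <- rbeta(n_cells, mito_shape1, mito_shape2)
  data.frame(barcode = barcode, true_isotype = true_iso,
             is_doublet = is_doublet, second_isotype = second,
             library_size = ls1 + ls2,
             library_size_second = ifelse(is_doublet, ls2, NA_integer_),
             mito_fraction = mito,
             background_fraction = background_fraction,
             stringsAsFactors = FALSE)
}

## Draw read start offsets (transcript coordinates) for one exon.
draw_offsets <- function(n, n_offsets, position_bias, bias_rate) {
  if (position_bias == "uniform") return(sample.int(n_offsets, n,
                                                    replace = TRUE))
  ## 3'-geometric: distance from the 3'-most valid start is truncated
  ## geometric with rate bias_rate.
  d <- seq_len(n_offsets) - 1L
  w <- (1 - bias_rate)^d
  n_offsets - sample.int(n_offsets, n, replace = TRUE, prob = w) + 1L
}

offset_weights <- function(n_offsets, position_bias, bias_rate) {
  if (position_bias == "uniform") return(rep(1 / n_offsets, n_offsets))
  d <- (n_offsets - seq_len(n_offsets))
  w <- (1 - bias_rate)^d
  w / sum(w)
}

#' Simulate barcode/UMI-tagged 3' reads from donor alleles
#'
#' Each molecule is drawn from the terminal exon of the cell's true isotype
#' allele in the *donor* panel (doublets draw from both isotypes, split
#' between the two component library sizes).  Start positions follow either
#' a uniform or a 3'-concentrated truncated-geometric law; substitution
#' sequencing errors are i.i.d. per base; PCR copies (exact duplicates
#' sharing barcode/UMI) are appended per molecule with count
#' 1 + Poisson(`pcr_duplication_mean` - 1).
#'
#' @param panel Donor `AllelePanel` (the sample's own alleles).
#' @param cells A `CellTruthTable` from [simulate_cells()].
#' @param read_length Read length (<= terminal exon length of every gene).
#' @param error_rate Per-base substitution error probability.
#' @param position_bias `"3prime-geometric"` or `"uniform"`.
#' @param bias_rate Geometric rate of the 3' bias.
#' @param pcr_duplication_mean Mean total copies per molecule (>= 1).
#' @param seed Integer seed.
#' @return A `ReadSet` data frame: `read_id`, `barcode`, `umi` (12-mer),
#'   `seq`, `true_gene`, `true_offset`, `is_pcr_copy`.
#' @export
simulate_reads <- function(panel, cells, read_length = 90L,
                           error_rate = 0.005,
                           position_bias = c("3prime-geometric", "uniform"),
                           bias_rate = 0.03, pcr_duplication_mean = 1.5,
                           seed = 1L) {
  position_bias <- match.arg(position_bias)
  stopifnot(pcr_duplication_mean >= 1)
  set.seed(seed)
  genes <- vapply(panel$genes, `[[`, "", "gene_id")
  exons <- vapply(genes, function(g) terminal_exon_seq(panel, g), "")
  if (any(read_length > nchar(exons)))
    stop("read_length exceeds a terminal exon length")

  ## Per-molecule gene and cell: doublets contribute two blocks.
  n1 <- ifelse(cells$is_doublet,
               cells$library_size - cells$library_size_second,
               cells$library_size)
  n2 <- ifelse(cells$is_doublet, cells$library_size_second, 0L)
  cell_idx <- c(rep(seq_len(nrow(cells)), n1),
                rep(seq_len(nrow(cells)), n2))
  gene <- c(rep(cells$true_isotype, n1), rep(cells$second_isotype, n2))
  if (!all(gene %in% genes))
    stop("cell truth references genes absent from the donor panel")
  n_mol <- length(gene)

  ## Offsets per gene (exons may differ in length).
  offset <- integer(n_mol)
  for (g in unique(gene)) {
    idx <- which(gene == g)
    n_off <- nchar(exons[[g]]) - read_length + 1L
    offset[idx] <- draw_offsets(length(idx), n_off, position_bias, bias_rate)
  }
  seqs <- substring(exons[gene], offset, offset + read_length - 1L)

  ## Sequencing errors: i.i.d. substitutions.
  if (error_rate > 0) {
    nerr <- rbinom(n_mol, read_length, error_rate)
    for (i in which(nerr > 0L)) {
      ch <- seq_chars(seqs[i])
      at <- sample.int(read_length, nerr[i])
      ch[at] <- alt_base(ch[at], sample(1:3, nerr[i], replace = TRUE))
      seqs[i] <- paste0(ch, collapse = "")
    }
  }

  umi <- random_dna(n_mol, 12L)
  reads <- data.frame(
    read_id = sprintf("m%07d", seq_len(n_mol)),
    barcode = cells$barcode[cell_idx], umi = umi, seq = seqs,
    true_gene = gene, true_offset = offset, is_pcr_copy = FALSE,
    stringsAsFactors = FALSE)

  if (pcr_duplication_mean > 1) {
    extra <- rpois(n_mol, pcr_duplication_mean - 1)
    if (any(extra > 0L)) {
      idx <- rep(seq_len(n_mol), extra)
      copies <- reads[idx, , drop = FALSE]
      copies$is_pcr_copy <- TRUE
      copy_no <- sequence(extra[extra > 0L])
      copies$read_id <- paste0(copies$read_id, "_c", copy_no)
      reads <- rbind(reads, copies)
      rownames(reads) <- NULL
    }
  }
  reads
}

#' Background (non-immunoglobulin) counts for a simulated matrix
#'
#' Real ASC transcriptomes carry mitochondrial, ribosomal and housekeeping
#' reads alongside the dominant immunoglobulin signal; QC and the >10\% Ig
#' ASC rule act on those totals.  This builds a deterministic-given-seed
#' sparse block of background counts per cell, scaled so that background
#' makes up each cell's `background_fraction` of its total and the
#' mitochondrial genes its `mito_fraction`.
#'
#' @param cells A `CellTruthTable`.
#' @param iso_counts Named integer vector of per-barcode isotype (effective)
#'   counts the background is scaled against.
#' @param n_housekeeping,n_ribo,n_mito Numbers of background feature ids
#'   (`HK*`, `RPL*`, `MT-*`).
#' @param seed Integer seed.
#' @return Sparse feature-by-barcode `Matrix::dgCMatrix`.
#' @export
simulate_background_counts <- function(cells, iso_counts,
                                       n_housekeeping = 40L, n_ribo = 8L,
                                       n_mito = 3L, seed = 1L) {
  set.seed(seed)
  feats <- c(sprintf("HK%02d", seq_len(n_housekeeping)),
             sprintf("RPL%d", seq_len(n_ribo)),
             sprintf("MT-%d", seq_len(n_mito)))
  bc <- cells$barcode
  iso <- iso_counts[bc]
  iso[is.na(iso)] <- 0L
  bgf <- cells$background_fraction
  total <- ifelse(bgf < 1, iso / pmax(1e-9, 1 - bgf), 0)
  n_mt <- as.integer(round(total * cells$mito_fraction))
  n_bg <- pmax(0L, as.integer(round(total * bgf)) - n_mt)
  counts <- matrix(0L, nrow = length(feats), ncol = length(bc),
                   dimnames = list(feats, bc))
  w_hk <- runif(n_housekeeping + n_ribo, 0.5, 1.5)
  for (j in seq_along(bc)) {
    if (n_bg[j] > 0L)
      counts[seq_len(n_housekeeping + n_ribo), j] <-
        rmultinom(1L, n_bg[j], w_hk)[, 1L]
    if (n_mt[j] > 0L)
      counts[n_housekeeping + n_ribo + seq_len(n_mito), j] <-
        rmultinom(1L, n_mt[j], rep(1, n_mito))[, 1L]
  }
  methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
}
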