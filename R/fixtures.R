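## Fixture I/O ------------------------------------------------------------
##
## Plain-text fixtures: panel FASTA+GTF per reference, reads as a TSV with
## truth columns and as 10x-style paired FASTQ (R1 = barcode+UMI, R2 =
## cDNA, Phred+33 uniform quality "I"), truth tables as TSV.  Everything
## round-trips bit-exactly through the readers below.

#' Write a complete synthetic fixture set
#'
#' @param panels Named list of `AllelePanel`s (typically the pair from
#'   [build_allele_panel()]).
#' @param cells A `CellTruthTable`.
#' @param reads A `ReadSet` data frame.
#' @param out_dir Output directory; refuses to overwrite a non-empty
#'   directory unless `overwrite = TRUE`.
#' @param overwrite Logical.
#' @return Invisibly, a named character vector of paths.
#' @export
write_fixtures <- function(panels, cells, reads, out_dir,
                           overwrite = FALSE) {
  check_outdir(out_dir, overwrite, pattern = ".")
  paths <- c()
  for (p in panels) paths <- c(paths, write_panel(p, out_dir,
                                                  overwrite = TRUE))
  ctsv <- file.path(out_dir, "cells.tsv")
  write.table(cells, ctsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rtsv <- file.path(out_dir, "reads.tsv")
  write.table(reads, rtsv, sep = "\t", quote = FALSE, row.names = FALSE)
  fq <- write_reads_fastq(reads, file.path(out_dir, "reads_R1.fastq"),
                          file.path(out_dir, "reads_R2.fastq"))
  invisible(c(paths, cells = ctsv, reads = rtsv, fq))
}

#' Write reads as 10x-style paired FASTQ
#' @param reads A `ReadSet` data frame.
#' @param r1,r2 Output paths (R1 = 16 bp barcode + 12 bp UMI; R2 = cDNA).
#' @export
write_reads_fastq <- function(reads, r1, r2) {
  s1 <- Biostrings::DNAStringSet(paste0(reads$barcode, reads$umi))
  s2 <- Biostrings::DNAStringSet(reads$seq)
  names(s1) <- names(s2) <- reads$read_id
  for (x in list(list(s1, r1), list(s2, r2))) {
    q <- Biostrings::BStringSet(strrep("I", Biostrings::width(x[[1L]])))
    Biostrings::writeXStringSet(x[[1L]], x[[2L]], format = "fastq",
                                qualities = q)
  }
  invisible(c(R1 = r1, R2 = r2))
}

#' Read a reads TSV back
#' @param path Path written by [write_fixtures()].
#' @return A `ReadSet` data frame.
#' @export
read_reads_tsv <- function(path) {
  read.delim(path, colClasses = c(
    read_id = "character", barcode = "character", umi = "character",
    seq = "character", true_gene = "character", true_offset = "integer",
    is_pcr_copy = "logical"))
}

#' Read paired FASTQ back into a `ReadSet` (without truth columns)
#' @param r1,r2 FASTQ paths.
#' @return Data frame with `read_id`, `barcode`, `umi`, `seq`.
#' @export
read_reads_fastq <- function(r1, r2) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
  tag <- as.character(s1)
  data.frame(read_id = names(s1), barcode = substr(tag, 1L, 16L),
             umi = substr(tag, 17L, 28L), seq = as.character(s2),
             stringsAsFactors = FALSE)
}

#' Read a cell truth table back
#' @param path Path written by [write_fixtures()].
#' @return A `CellTruthTable` data frame.
#' @export
read_cells_tsv <- function(path) {
  read.delim(path, colClasses = c(
    barcode = "character", true_isotype = "character",
    is_doublet = "logical", second_isotype = "character",
    library_size = "integer", library_size_second = "integer",
    mito_fraction = "numeric", background_fraction = "numeric"))
}
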