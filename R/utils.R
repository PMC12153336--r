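#' @useDynLib isoref, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rpois rlnorm rbeta rmultinom runif setNames
#'   pbinom qbinom pnorm median cor complete.cases
#' @importFrom utils write.table read.delim head combn
NULL

DNA_BASES <- c("A", "C", "G", "T")

## Deterministic alternative base: cyclic shift within ACGT.
alt_base <- function(base, k = 1L) {
  i <- match(base, DNA_BASES)
  if (anyNA(i)) stop("non-ACGT base: ", paste(base[is.na(i)], collapse = ","))
  DNA_BASES[((i - 1L + k) %% 4L) + 1L]
}

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Split a sequence string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

## Derive a stage seed from a master seed; keeps results within 32-bit range.
derive_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1009L + as.integer(stage) * 7L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
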