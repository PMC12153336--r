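## Shipped study configurations ------------------------------------------
##
## Synthetic variant-placement specs that reproduce, by construction, the
## qualitative sequence patterns driving the reference-ancestry artifact:
## an IgG-subclass pair whose donor IGHG2 allele is closer to the wrong
## paralog of the mismatched reference over a 3' window, and an IgA-subclass
## pair whose terminal tail is identical in the matched reference (so reads
## there multi-map) but divergent in the other.  All positions refer to a
## 300 bp terminal exon whose coding compartment ends at 180 (120 bp 3'-UTR).

#' IgG1/IgG2 reference-swap configuration
#'
#' Reference B (the ancestry-matched, T2T-like reference) separates the two
#' paralogs by seven substitutions inside the 3'-terminal 90 bp; reference A
#' (the mismatched, hg38-like reference) instead carries two substitutions
#' on its IGHG2 allele and one on its IGHG1 allele relative to the donor
#' IGHG2 allele.  A 3'-end read from a donor IGHG2 transcript therefore has
#' mismatch counts 2 / 1 / 0 / 7 against IGHG2-A / IGHG1-A / IGHG2-B /
#' IGHG1-B and flips its assignment from IGHG2 (under B) to IGHG1 (under A).
#'
#' @return A [pair_spec()].
#' @export
ighg_swap_spec <- function() {
  pair_spec(
    pair_id = "IGHG1/IGHG2", gene1 = "IGHG1", gene2 = "IGHG2",
    variants = data.frame(
      ref = c(rep("refB", 7L), "refA", "refA", "refA"),
      pos = c(215L, 225L, 235L, 245L, 255L, 265L, 285L, 230L, 250L, 270L),
      carrier = c(rep("gene1", 7L), "gene1", "gene2", "gene2")))
}

#' IgA1/IgA2 shared-tail configuration
#'
#' Reference B separates the paralogs by a single interior substitution
#' (position 120); 3' of it the two alleles are identical, so all terminal
#' reads multi-map under B.  Reference A carries nine substitutions in that
#' same 3' block (one on IGHA1 at 155, eight on IGHA2 between 240 and 282),
#' so terminal reads from a donor matched to B are pulled onto IGHA1 under A.
#'
#' @return A [pair_spec()].
#' @export
igha_shared_tail_spec <- function() {
  pair_spec(
    pair_id = "IGHA1/IGHA2", gene1 = "IGHA1", gene2 = "IGHA2",
    variants = data.frame(
      ref = c("refB", rep("refA", 9L)),
      pos = c(120L, 155L, 240L, 246L, 252L, 258L, 264L, 270L, 276L, 282L),
      carrier = c("gene1", "gene1", rep("gene2", 8L))))
}

#' Cross-reference allele-divergence configuration
#'
#' Singleton gene specs whose alleles differ between the two references in
#' the compartment pattern seen for the IgG subclass genes: five coding plus
#' eight UTR substitutions (IGHG1-like), one coding plus three UTR
#' (IGHG2-like), a single substitution near the UTR end (IGHG3-like), and a
#' gene duplicated in reference B with copy-specific divergence
#' (IGHG4-like: copy 1 two coding / zero UTR, copy 2 one coding / six UTR).
#'
#' @return A list of [singleton_spec()] objects.
#' @export
reference_divergence_spec <- function() {
  list(
    singleton_spec("IGHG1", copies = list(
      refA = list(data.frame(pos = integer(0))),
      refB = list(data.frame(pos = c(20L, 50L, 80L, 110L, 140L,
                                     190L, 200L, 210L, 220L, 230L,
                                     240L, 260L, 280L))))),
    singleton_spec("IGHG2", copies = list(
      refA = list(data.frame(pos = integer(0))),
      refB = list(data.frame(pos = c(90L, 200L, 240L, 280L))))),
    singleton_spec("IGHG3", copies = list(
      refA = list(data.frame(pos = integer(0))),
      refB = list(data.frame(pos = 297L)))),
    singleton_spec("IGHG4", copies = list(
      refA = list(data.frame(pos = integer(0))),
      refB = list(data.frame(pos = c(60L, 130L)),
                  data.frame(pos = c(100L, 185L, 205L, 225L, 245L,
                                     265L, 285L))))))
}

#' Worked single-read example of the assignment flip
#'
#' Builds the [ighg_swap_spec()] panels and extracts the 3'-terminal read of
#' the donor IGHG2 allele (donor matched to reference B) together with the
#' four candidate regions, an illustrative alignment of the assignment flip:
#' minimum mismatch counts 2, 1, 0 and 7 against IGHG2-refA, IGHG1-refA,
#' IGHG2-refB and IGHG1-refB.
#'
#' @param seed Seed forwarded to [build_allele_panel()].
#' @param read_length Read length (must not exceed the exon).
#' @return List with elements `read`, `regions` (labelled data frame of the
#'   four region sequences) and `panels`.
#' @export
ighg_worked_example <- function(seed = 1L, read_length = 90L) {
  panels <- build_allele_panel(list(ighg_swap_spec()), seed = seed)
  exon <- terminal_exon_seq(panels$refB, "IGHG2")
  L <- nchar(exon)
  read <- substr(exon, L - read_length + 1L, L)
  regions <- do.call(rbind, lapply(names(panels), function(r) {
    p <- panel_regions(panels[[r]], genes = c("IGHG1", "IGHG2"))
    p$region_id <- paste0(p$gene_id, "-", r)
    p$reference <- r
    p
  }))
  list(read = read, regions = regions, panels = panels)
}
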