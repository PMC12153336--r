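## Allele panels ---------------------------------------------------------
##
## An AllelePanel holds, for one genome reference, the constant-region exon
## sequences (alleles) of a set of immunoglobulin isotype genes.  Sequences
## are stored transcript-oriented (5'->3' of the mRNA); genomic orientation
## is applied only when writing/reading FASTA+GTF.

#' Declare a paralog pair with placed variants
#'
#' Describes two paralogous isotype genes (e.g. IGHG1/IGHG2) sharing one
#' random backbone exon, together with the substitutions that distinguish
#' them within each reference and, implicitly, across references.
#'
#' @param pair_id Identifier for the pair.
#' @param gene1,gene2 Gene ids of the two paralogs.
#' @param variants Data frame with columns `ref` (reference name), `pos`
#'   (1-based position in the terminal exon), `carrier` (one of `"gene1"`,
#'   `"gene2"`, `"both"`: which paralog carries the non-backbone base) and
#'   optionally explicit `base1`/`base2` columns.
#' @param strand Strand of both genes (`"+"` or `"-"`).
#' @param exon_length,utr_length Optional per-pair overrides of the panel
#'   defaults.
#' @return A `pair_spec` list consumed by [build_allele_panel()].
#' @export
pair_spec <- function(pair_id, gene1, gene2, variants = NULL, strand = "-",
                      exon_length = NULL, utr_length = NULL) {
  if (is.null(variants))
    variants <- data.frame(ref = character(0), pos = integer(0),
                           carrier = character(0))
  stopifnot(all(c("ref", "pos", "carrier") %in% names(variants)))
  structure(list(pair_id = pair_id, gene1 = gene1, gene2 = gene2,
                 variants = variants, strand = strand,
                 exon_length = exon_length, utr_length = utr_length),
            class = "pair_spec")
}

#' Declare a single (unpaired) gene with per-reference allele copies
#'
#' Used for cross-reference comparisons of one gene, including duplicated
#' copies within one reference (as for IGHG4, present twice in some
#' assemblies).  Each copy is the shared backbone plus the listed
#' substitutions.
#'
#' @param symbol Gene symbol shared by all copies.
#' @param copies Named list (one element per reference) of lists of data
#'   frames with column `pos` (and optional `base`); one data frame per copy.
#' @param strand Strand.
#' @param exon_length,utr_length Optional overrides.
#' @return A `singleton_spec` list consumed by [build_allele_panel()].
#' @export
singleton_spec <- function(symbol, copies, strand = "-",
                           exon_length = NULL, utr_length = NULL) {
  structure(list(symbol = symbol, copies = copies, strand = strand,
                 exon_length = exon_length, utr_length = utr_length),
            class = "singleton_spec")
}

TERMINAL_EXON <- "CH3-CHS"

## Compose one allele from backbone + a pos->base map; checks consistency.
apply_variants <- function(backbone, pos, base, what) {
  if (length(pos)) {
    if (any(pos < 1L | pos > length(backbone)))
      stop("placement error: position outside exon in ", what)
    dup <- duplicated(pos)
    if (any(dup)) {
      for (p in unique(pos[dup])) {
        if (length(unique(base[pos == p])) > 1L)
          stop("placement error: inconsistent bases at position ", p,
               " in ", what)
      }
    }
    backbone[pos] <- base
  }
  paste0(backbone, collapse = "")
}

#' Build a pair of allele panels from variant placement specs
#'
#' Generates, deterministically from `seed`, two [allele panels][AllelePanel]
#' (one per reference) sharing gene structure: each paralog pair draws one
#' random backbone exon, then the declared substitutions -- and no others --
#' are applied per reference and per gene.  Where no explicit base is given,
#' the carrier gene receives a deterministic alternative base (cyclic
#' A->C->G->T shift; `carrier = "both"` shifts twice for the second gene).
#'
#' @param specs List of [pair_spec()] objects.
#' @param base_exon_length Length of the terminal (CH3-CHS-like) exon.
#' @param utr_length Length of the 3'-UTR tail of that exon; the coding
#'   compartment ends at `base_exon_length - utr_length`.
#' @param seed Integer seed.
#' @param ref_names Names of the two references (first plays the role of the
#'   ancestry-mismatched reference in the shipped experiment specs).
#' @param singletons Optional list of [singleton_spec()] objects.
#' @return Named list of two `AllelePanel` objects.
#' @export
build_allele_panel <- function(specs, base_exon_length = 300L,
                               utr_length = 120L, seed = 1L,
                               ref_names = c("refA", "refB"),
                               singletons = list()) {
  stopifnot(length(ref_names) == 2L, utr_length < base_exon_length)
  if (inherits(specs, "pair_spec")) specs <- list(specs)
  set.seed(seed)
  panels <- lapply(ref_names, function(r)
    structure(list(reference_name = r, genes = list(), pairs = list()),
              class = "AllelePanel"))
  names(panels) <- ref_names

  for (sp in specs) {
    len <- sp$exon_length %||% base_exon_length
    utr <- sp$utr_length %||% utr_length
    backbone <- seq_chars(random_dna(1L, len))
    v <- sp$variants
    if (nrow(v) && !all(v$ref %in% ref_names))
      stop("unknown reference in pair_spec '", sp$pair_id, "'")
    for (r in ref_names) {
      vr <- v[v$ref == r, , drop = FALSE]
      bases <- lapply(c("gene1", "gene2"), function(slot) {
        b <- backbone[vr$pos]
        if (!is.null(vr$base1) && slot == "gene1") explicit <- vr$base1
        else if (!is.null(vr$base2) && slot == "gene2") explicit <- vr$base2
        else explicit <- rep(NA_character_, nrow(vr))
        carried <- vr$carrier == slot | vr$carrier == "both"
        k <- ifelse(vr$carrier == "both" & slot == "gene2", 2L, 1L)
        b[carried] <- alt_base(backbone[vr$pos[carried]], k[carried])
        b[!is.na(explicit)] <- explicit[!is.na(explicit)]
        b
      })
      if (any(bases[[1L]] == bases[[2L]]))
        stop("placement error: declared variant with identical bases in '",
             sp$pair_id, "'")
      for (i in 1:2) {
        gid <- c(sp$gene1, sp$gene2)[i]
        seqr <- apply_variants(backbone, vr$pos, bases[[i]],
                               paste0(gid, "/", r))
        panels[[r]]$genes[[gid]] <- list(
          gene_id = gid, symbol = gid, strand = sp$strand,
          allele_label = paste0(gid, "*", r),
          exons = setNames(seqr, TERMINAL_EXON),
          terminal_exon = TERMINAL_EXON, coding_end = len - utr,
          pair_id = sp$pair_id)
      }
      panels[[r]]$pairs[[sp$pair_id]] <- c(sp$gene1, sp$gene2)
    }
  }

  for (sg in singletons) {
    len <- sg$exon_length %||% base_exon_length
    utr <- sg$utr_length %||% utr_length
    backbone <- seq_chars(random_dna(1L, len))
    for (r in ref_names) {
      copies <- sg$copies[[r]]
      if (is.null(copies)) copies <- list(data.frame(pos = integer(0)))
      for (ci in seq_along(copies)) {
        cv <- copies[[ci]]
        base <- if (!is.null(cv$base)) cv$base else alt_base(backbone[cv$pos])
        gid <- if (length(copies) > 1L) paste0(sg$symbol, "_", ci) else
          sg$symbol
        seqr <- apply_variants(backbone, cv$pos, base,
                               paste0(gid, "/", r))
        panels[[r]]$genes[[gid]] <- list(
          gene_id = gid, symbol = sg$symbol, strand = sg$strand,
          allele_label = paste0(sg$symbol, "*", r, ".", ci),
          exons = setNames(seqr, TERMINAL_EXON),
          terminal_exon = TERMINAL_EXON, coding_end = len - utr,
          pair_id = NA_character_)
      }
    }
  }
  for (p in panels) validate_panel(p)
  panels
}

validate_panel <- function(panel) {
  ids <- vapply(panel$genes, `[[`, "", "gene_id")
  if (anyDuplicated(ids)) stop("duplicate gene_ids in panel")
  for (g in panel$genes) {
    if (any(!nzchar(g$exons))) stop("empty exon sequence in ", g$gene_id)
    if (any(grepl("[^ACGT]", g$exons)))
      stop("non-ACGT/lower-case sequence in ", g$gene_id)
  }
  for (pr in panel$pairs) {
    n1 <- length(panel$genes[[pr[1L]]]$exons)
    n2 <- length(panel$genes[[pr[2L]]]$exons)
    if (n1 != n2) stop("paralog pair with unequal exon counts")
  }
  invisible(panel)
}

#' @export
print.AllelePanel <- function(x, ...) {
  cat("AllelePanel '", x$reference_name, "': ", length(x$genes),
      " gene(s), ", length(x$pairs), " declared pair(s)\n", sep = "")
  for (g in x$genes)
    cat(sprintf("  %-10s %s  %s  exon %dbp (coding 1-%d)\n", g$gene_id,
                g$strand, g$allele_label, nchar(g$exons[[g$terminal_exon]]),
                g$coding_end))
  invisible(x)
}

#' Terminal-exon sequence of one gene
#' @param panel An `AllelePanel`.
#' @param gene_id Gene identifier.
#' @return Transcript-oriented terminal exon sequence (character scalar).
#' @export
terminal_exon_seq <- function(panel, gene_id) {
  g <- panel$genes[[gene_id]]
  if (is.null(g)) stop("gene '", gene_id, "' not in panel ",
                       panel$reference_name)
  unname(g$exons[[g$terminal_exon]])
}

## Genomic layout of a panel on one synthetic contig (1-based closed).
panel_layout <- function(panel, contig = "IGHsyn", flank = 100L,
                         intron = 50L) {
  rows <- list()
  cursor <- flank + 1L
  for (g in panel$genes) {
    ex <- g$exons
    ord <- seq_along(ex)
    if (g$strand == "-") ord <- rev(ord)  # transcript 5' is genomic high
    for (i in ord) {
      len <- nchar(ex[[i]])
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g$gene_id, symbol = g$symbol, exon = names(ex)[i],
        chrom = contig, start = cursor, end = cursor + len - 1L,
        strand = g$strand, coding_end = g$coding_end,
        terminal = names(ex)[i] == g$terminal_exon,
        allele_label = g$allele_label, stringsAsFactors = FALSE)
      cursor <- cursor + len + intron
    }
    cursor <- cursor - intron + flank
  }
  lay <- do.call(rbind, rows)
  attr(lay, "contig_length") <- cursor - flank + flank  # trailing flank
  lay
}

panel_contig_seq <- function(panel, layout) {
  n <- attr(layout, "contig_length")
  contig <- rep("N", n)
  for (i in seq_len(nrow(layout))) {
    g <- panel$genes[[layout$gene_id[i]]]
    s <- g$exons[[layout$exon[i]]]
    if (layout$strand[i] == "-") s <- revcomp(s)
    contig[layout$start[i]:layout$end[i]] <- seq_chars(s)
  }
  paste0(contig, collapse = "")
}

layout_granges <- function(panel, layout) {
  gr <- GenomicRanges::GRanges(
    seqnames = layout$chrom,
    ranges = IRanges::IRanges(layout$start, layout$end),
    strand = layout$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "isoref", type = "exon",
    phase = NA_integer_,
    gene_id = layout$gene_id, gene_name = layout$symbol,
    transcript_id = paste0(layout$gene_id, "-t1"),
    exon_id = paste0(layout$gene_id, ":", layout$exon),
    allele_label = layout$allele_label)
  gr
}

#' Write a panel as FASTA + GTF
#'
#' The FASTA holds one synthetic contig in genomic orientation (gene gaps
#' filled with N); the GTF (1-based, closed) carries `exon` records with
#' `gene_id`, `transcript_id` and `exon_id` attributes plus `CDS` records
#' marking the coding compartment of the terminal exon.
#'
#' @param panel An `AllelePanel`.
#' @param dir Output directory (created if absent).
#' @param overwrite Refuse to write into a non-empty existing directory
#'   unless `TRUE`.
#' @return Invisibly, the paths written.
#' @export
write_panel <- function(panel, dir, overwrite = FALSE) {
  check_outdir(dir, overwrite, pattern = paste0("^", panel$reference_name))
  lay <- panel_layout(panel)
  fa <- file.path(dir, paste0(panel$reference_name, ".fa"))
  gtf <- file.path(dir, paste0(panel$reference_name, ".gtf"))
  contig <- Biostrings::DNAStringSet(panel_contig_seq(panel, lay))
  names(contig) <- lay$chrom[1L]
  Biostrings::writeXStringSet(contig, fa, width = 60L)

  gr <- layout_granges(panel, lay)
  cds <- lay[lay$terminal & !is.na(lay$coding_end), , drop = FALSE]
  if (nrow(cds)) {
    cs <- ifelse(cds$strand == "+", cds$start, cds$end - cds$coding_end + 1L)
    ce <- ifelse(cds$strand == "+", cds$start + cds$coding_end - 1L, cds$end)
    grc <- GenomicRanges::GRanges(cds$chrom, IRanges::IRanges(cs, ce),
                                  strand = cds$strand)
    S4Vectors::mcols(grc) <- S4Vectors::DataFrame(
      source = "isoref", type = "CDS", phase = 0L, gene_id = cds$gene_id,
      gene_name = cds$symbol, transcript_id = paste0(cds$gene_id, "-t1"),
      exon_id = paste0(cds$gene_id, ":", cds$exon, ":CDS"),
      allele_label = cds$allele_label)
    gr <- c(gr, grc)
  }
  rtracklayer::export(gr, gtf, format = "gtf")
  invisible(c(fasta = fa, gtf = gtf))
}

#' Read a panel back from FASTA + GTF
#'
#' Inverse of [write_panel()]: exon sequences are extracted from the contig
#' at the GTF coordinates, reverse-complemented for minus-strand genes, and
#' the coding compartment is recovered from the CDS records.
#'
#' @param fasta,gtf File paths.
#' @param reference_name Name to give the reconstructed panel.
#' @return An `AllelePanel`.
#' @export
read_panel <- function(fasta, gtf, reference_name = "panel") {
  contig <- Biostrings::readDNAStringSet(fasta)
  gr <- rtracklayer::import(gtf, format = "gtf")
  ex <- gr[gr$type == "exon"]
  cds <- gr[gr$type == "CDS"]
  genes <- list()
  for (gid in unique(ex$gene_id)) {
    e <- ex[ex$gene_id == gid]
    strand <- as.character(BiocGenerics::strand(e))[1L]
    ord <- order(BiocGenerics::start(e),
                 decreasing = identical(strand, "-"))
    e <- e[ord]
    seqs <- vapply(seq_along(e), function(i) {
      s <- subseq(contig[[as.character(GenomicRanges::seqnames(e))[i]]],
                  BiocGenerics::start(e)[i], BiocGenerics::end(e)[i])
      s <- as.character(s)
      if (strand == "-") revcomp(s) else s
    }, "")
    exnames <- sub(paste0("^", gid, ":"), "", e$exon_id)
    term <- exnames[length(exnames)]
    coding_end <- NA_integer_
    cg <- cds[cds$gene_id == gid]
    if (length(cg)) coding_end <- sum(BiocGenerics::width(cg))
    genes[[gid]] <- list(
      gene_id = gid, symbol = e$gene_name[1L] %||% gid, strand = strand,
      allele_label = e$allele_label[1L] %||% NA_character_,
      exons = setNames(seqs, exnames), terminal_exon = term,
      coding_end = coding_end, pair_id = NA_character_)
  }
  structure(list(reference_name = reference_name, genes = genes,
                 pairs = list()), class = "AllelePanel")
}

subseq <- function(x, s, e) Biostrings::subseq(x, s, e)

check_outdir <- function(dir, overwrite, pattern = NULL) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  } else {
    existing <- list.files(dir, pattern = pattern)
    if (length(existing) && !overwrite)
      stop("output directory '", dir, "' already holds files; ",
           "set overwrite = TRUE")
  }
  invisible(dir)
}

#' Candidate alignment regions of a panel
#'
#' One region per gene: the terminal exon in transcript orientation.  The
#' `split_at`/`shared_gene` columns are `NA` here; [rescue_regions()] fills
#' them for a rescue annotation.
#'
#' @param panel An `AllelePanel`.
#' @param genes Optional subset of gene ids.
#' @return Data frame with columns `region_id`, `gene_id`, `seq`,
#'   `split_at`, `shared_gene`.
#' @export
panel_regions <- function(panel, genes = NULL) {
  gs <- panel$genes
  if (!is.null(genes)) gs <- gs[genes]
  data.frame(
    region_id = vapply(gs, `[[`, "", "gene_id"),
    gene_id = vapply(gs, `[[`, "", "gene_id"),
    seq = vapply(gs, function(g) unname(g$exons[[g$terminal_exon]]), ""),
    split_at = NA_integer_, shared_gene = NA_character_,
    row.names = NULL, stringsAsFactors = FALSE)
}
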