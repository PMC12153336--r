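test_that("allele panels contain the declared substitutions and no others", {
  # identity case: no variants anywhere
  sp0 <- pair_spec("P", "G1", "G2")
  p0 <- build_allele_panel(list(sp0), seed = 3)
  expect_identical(terminal_exon_seq(p0$refA, "G1"),
                   terminal_exon_seq(p0$refA, "G2"))
  expect_identical(terminal_exon_seq(p0$refA, "G1"),
                   terminal_exon_seq(p0$refB, "G1"))

  # 9 variants in refA, 0 in refB, checked by direct character comparison
  sp <- pair_spec("P", "G1", "G2", variants = data.frame(
    ref = "refA", pos = c(10L, 30L, 50L, 70L, 90L, 110L, 130L, 150L, 170L),
    carrier = "gene1"))
  p <- build_allele_panel(list(sp), seed = 4)
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_equal(ham(terminal_exon_seq(p$refA, "G1"),
                   terminal_exon_seq(p$refA, "G2")), 9)
  expect_equal(ham(terminal_exon_seq(p$refB, "G1"),
                   terminal_exon_seq(p$refB, "G2")), 0)

  # determinism
  p2 <- build_allele_panel(list(sp), seed = 4)
  expect_identical(p, p2)

  # inconsistent bases at one position are rejected
  bad <- pair_spec("P", "G1", "G2", variants = data.frame(
    ref = "refA", pos = c(10L, 10L), carrier = "gene1",
    base1 = c("A", "C"), base2 = c("G", "G")))
  expect_error(build_allele_panel(list(bad), seed = 1), "placement error")
})

test_that("the IgA-like fixture yields non-empty blue and orange regions", {
  panels <- build_allele_panel(list(igha_shared_tail_spec()), seed = 2)
  dec <- decompose_regions(panels, "IGHA1/IGHA2", read_length = 90)
  iv <- dec$intervals
  expect_true(any(iv$colour == "blue"))
  expect_true(any(iv$colour == "orange"))
  # blue block sits at the 3' end, orange around the interior variant
  expect_equal(max(iv$end[iv$colour == "blue"]), max(iv$end))
  expect_lt(max(iv$end[iv$colour == "orange"]),
            min(iv$start[iv$colour == "blue"]))
})

test_that("cell simulation reproduces the doublet model", {
  expect_error(simulate_cells(0, c(A = 1)), "positive")
  expect_error(simulate_cells(10, c(A = .5, B = .6)), "sum to 1")

  cells0 <- simulate_cells(200, c(IGHG1 = .5, IGHG2 = .5),
                           doublet_rate = 0, seed = 1)
  expect_false(any(cells0$is_doublet))
  expect_true(all(is.na(cells0$second_isotype)))

  cells <- simulate_cells(10000, c(IGHG1 = .5, IGHG2 = .5),
                          doublet_rate = 0.02, seed = 42)
  nd <- sum(cells$is_doublet)
  expect_gte(nd, qbinom(0.005, 10000, 0.02))
  expect_lte(nd, qbinom(0.995, 10000, 0.02))
  expect_false(anyDuplicated(cells$barcode) > 0)
  expect_true(all(cells$second_isotype[cells$is_doublet] !=
                    cells$true_isotype[cells$is_doublet]))

  # doublet library sizes about twice the singlet mean
  ratio <- mean(cells$library_size[cells$is_doublet]) /
    mean(cells$library_size[!cells$is_doublet])
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("reads are faithful substrings with the configured error law", {
  panels <- build_allele_panel(list(ighg_swap_spec()), seed = 5)
  cells <- simulate_cells(300, c(IGHG1 = .5, IGHG2 = .5),
                          doublet_rate = 0.05, seed = 6)
  reads <- simulate_reads(panels$refB, cells, error_rate = 0,
                          pcr_duplication_mean = 1, seed = 7)

  # conservation: one pre-duplication read per molecule
  expect_equal(nrow(reads), sum(cells$library_size))
  # exact substrings at the recorded offset; unique (barcode, UMI)
  exons <- vapply(c(IGHG1 = "IGHG1", IGHG2 = "IGHG2"),
                  function(g) terminal_exon_seq(panels$refB, g), "")
  expect_identical(reads$seq,
                   unname(substring(exons[reads$true_gene],
                                    reads$true_offset,
                                    reads$true_offset + 89)))
  expect_false(anyDuplicated(paste(reads$barcode, reads$umi)) > 0)

  # doublets draw from exactly their two truth genes
  dbl <- cells[cells$is_doublet, ][1, ]
  gset <- unique(reads$true_gene[reads$barcode == dbl$barcode])
  expect_setequal(gset, c(dbl$true_isotype, dbl$second_isotype))

  # error rate 0.01 at R = 90: mean mismatches ~ 0.9 within 3 SE
  big <- simulate_cells(1000, c(IGHG1 = 1), doublet_rate = 0,
                        libsize_log_mean = log(100), libsize_log_sd = 0.1,
                        seed = 8)
  er <- simulate_reads(panels$refB, big, error_rate = 0.01,
                       pcr_duplication_mean = 1, seed = 9)
  truth <- substring(exons[er$true_gene], er$true_offset,
                     er$true_offset + 89)
  mm <- mapply(function(a, b) sum(strsplit(a, "")[[1]] !=
                                    strsplit(b, "")[[1]]), er$seq, truth)
  n <- length(mm)
  se <- sqrt(90 * 0.01 * 0.99 / n)
  expect_lt(abs(mean(mm) - 0.9), 3 * se + 1e-9)

  # 3' geometric bias shifts start offsets towards the 3' end
  u <- simulate_reads(panels$refB, big, error_rate = 0,
                      position_bias = "uniform",
                      pcr_duplication_mean = 1, seed = 10)
  g3 <- simulate_reads(panels$refB, big, error_rate = 0,
                       position_bias = "3prime-geometric",
                       pcr_duplication_mean = 1, seed = 10)
  wt <- wilcox.test(g3$true_offset, u$true_offset, alternative = "greater")
  expect_lt(wt$p.value, 1e-6)
})

test_that("fixtures round-trip bit-exactly", {
  panels <- build_allele_panel(list(igha_shared_tail_spec()), seed = 11)
  cells <- simulate_cells(20, c(IGHA1 = .5, IGHA2 = .5), doublet_rate = 0,
                          libsize_log_mean = log(5), seed = 12)
  reads <- simulate_reads(panels$refB, cells, error_rate = 0.01,
                          pcr_duplication_mean = 1.3, seed = 13)
  reads <- head(reads, 100)
  dir <- withr::local_tempdir()
  write_fixtures(panels, cells, reads, file.path(dir, "fx"))

  # refusal to clobber
  expect_error(write_fixtures(panels, cells, reads, file.path(dir, "fx")),
               "overwrite")

  r2 <- read_reads_tsv(file.path(dir, "fx", "reads.tsv"))
  expect_identical(r2, reads)
  fq <- read_reads_fastq(file.path(dir, "fx", "reads_R1.fastq"),
                         file.path(dir, "fx", "reads_R2.fastq"))
  expect_identical(fq$barcode, reads$barcode)
  expect_identical(fq$umi, reads$umi)
  expect_identical(fq$seq, reads$seq)
  c2 <- read_cells_tsv(file.path(dir, "fx", "cells.tsv"))
  expect_equal(c2$barcode, cells$barcode)
  expect_equal(c2$library_size, cells$library_size)

  # GTF + FASTA round-trip: sequences and coordinates as declared
  for (r in c("refA", "refB")) {
    p2 <- read_panel(file.path(dir, "fx", paste0(r, ".fa")),
                     file.path(dir, "fx", paste0(r, ".gtf")),
                     reference_name = r)
    for (g in names(panels[[r]]$genes)) {
      expect_identical(terminal_exon_seq(p2, g),
                       terminal_exon_seq(panels[[r]], g))
      expect_identical(p2$genes[[g]]$coding_end,
                       panels[[r]]$genes[[g]]$coding_end)
    }
    lay <- isoref:::panel_layout(panels[[r]])
    gtf <- rtracklayer::import(file.path(dir, "fx", paste0(r, ".gtf")))
    ex <- gtf[gtf$type == "exon"]
    ex <- ex[match(lay$gene_id, ex$gene_id)]
    expect_equal(BiocGenerics::start(ex), lay$start)
    expect_equal(BiocGenerics::end(ex), lay$end)
  }

  # empty read set still writes valid files
  empty <- reads[0, ]
  write_fixtures(panels, cells, empty, file.path(dir, "fx0"))
  e2 <- read_reads_tsv(file.path(dir, "fx0", "reads.tsv"))
  expect_equal(nrow(e2), 0)
  expect_identical(names(e2), names(reads))
})

test_that("identical seeds and configs give byte-identical fixtures", {
  root <- withr::local_tempdir()
  build <- function(dir) {
    panels <- build_allele_panel(list(ighg_swap_spec()), seed = 21)
    cells <- simulate_cells(30, c(IGHG1 = .6, IGHG2 = .4),
                            doublet_rate = 0.1, seed = 22)
    reads <- simulate_reads(panels$refB, cells, error_rate = 0.02,
                            pcr_duplication_mean = 1.7, seed = 23)
    write_fixtures(panels, cells, reads, dir)
    dir
  }
  d1 <- build(file.path(root, "a")); d2 <- build(file.path(root, "b"))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})
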