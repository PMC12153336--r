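test_that("shared terminal regions are maximal identical suffixes", {
  s <- "ACGTACGTAA"
  same <- find_shared_terminal_region(s, s)
  expect_equal(same$shared_length, nchar(s))
  expect_equal(same$boundary_a, 1)

  last <- find_shared_terminal_region("ACGTACGTAA", "ACGTACGTAC")
  expect_equal(last$shared_length, 0)

  # IgA-like fixture: shared segment from the base after the last refB
  # variant to the exon end, verified by a direct suffix scan
  pp <- build_allele_panel(list(igha_shared_tail_spec()), seed = 2)
  s1 <- terminal_exon_seq(pp$refB, "IGHA1")
  s2 <- terminal_exon_seq(pp$refB, "IGHA2")
  sh <- find_shared_terminal_region(s1, s2)
  suffix_scan <- 0
  while (suffix_scan < nchar(s1) &&
         substr(s1, nchar(s1) - suffix_scan, nchar(s1) - suffix_scan) ==
         substr(s2, nchar(s2) - suffix_scan, nchar(s2) - suffix_scan))
    suffix_scan <- suffix_scan + 1
  expect_equal(sh$shared_length, suffix_scan)
  expect_equal(sh$boundary_a, 121)
})

test_that("exon splitting is strand-correct and tiles the original exon", {
  # plus-strand toy: exon at 101-200, identity boundary at transcript 61
  mk <- function(strand) {
    sp <- pair_spec("P", "G1", "G2",
                    variants = data.frame(ref = "refB", pos = 60L,
                                          carrier = "gene1"),
                    strand = strand, exon_length = 100L, utr_length = 30L)
    build_allele_panel(list(sp), seed = 44)$refB
  }
  plus <- mk("+")
  ann <- build_rescue_annotation(plus, c("G1", "G2"), "GM")
  expect_equal(ann$splits$boundary, c(61, 61))
  r <- ann$records
  own <- r[r$gene_id == "G1", ]           # G1's exon spans 101-200
  shr <- r[r$gene_id == "GM" & r$start <= 300, ]
  expect_equal(c(own$start, own$end), c(101, 160))
  expect_equal(c(shr$start, shr$end), c(161, 200))

  minus <- mk("-")
  annm <- build_rescue_annotation(minus, c("G1", "G2"), "GM")
  own_m <- annm$records[annm$records$gene_id == "G1", ]
  shr_m <- annm$records[annm$records$gene_id == "GM" &
                          annm$records$end <= 300, ]
  # merged (transcript 3') segment occupies the low-coordinate side
  expect_lt(shr_m$end, own_m$start)
  expect_equal(shr_m$end - shr_m$start + 1, 40)

  # tiling: split lengths sum to the original exon length for both genes
  for (ann_i in list(ann, annm)) {
    for (g in c("G1", "G2")) {
      orig <- ann_i$original[ann_i$original$gene_id == g, ]
      segs <- ann_i$records[ann_i$records$start >= orig$start &
                              ann_i$records$end <= orig$end, ]
      expect_equal(sum(segs$end - segs$start + 1),
                   orig$end - orig$start + 1)
      expect_equal(min(segs$start), orig$start)
      expect_equal(max(segs$end), orig$end)
    }
  }

  # zero-length shared segment: annotation unchanged with a warning
  sp0 <- pair_spec("P", "G1", "G2",
                   variants = data.frame(ref = "refB", pos = 300L,
                                         carrier = "gene1"))
  p0 <- build_allele_panel(list(sp0), seed = 45)$refB
  expect_warning(a0 <- build_rescue_annotation(p0, c("G1", "G2"), "GM"),
                 "unchanged")
  expect_equal(a0$records, a0$original)
})

test_that("rescue annotations round-trip through the GTF reader", {
  pp <- build_allele_panel(list(igha_shared_tail_spec()), seed = 2)
  ann <- build_rescue_annotation(pp$refB, "IGHA1/IGHA2", "IGHA")
  dir <- withr::local_tempdir()
  write_panel(pp$refB, dir)
  write_rescue_gtf(ann, pp$refB, file.path(dir, "rescue.gtf"))
  gtf <- rtracklayer::import(file.path(dir, "rescue.gtf"))
  ex <- gtf[gtf$type == "exon"]
  expect_setequal(unique(ex$gene_id), c("IGHA1", "IGHA2", "IGHA"))
  expect_equal(sum(ex$gene_id == "IGHA"), 2)
  got <- as.data.frame(ex[ex$gene_id == "IGHA"])
  want <- ann$records[ann$records$gene_id == "IGHA", ]
  expect_setequal(got$start, want$start)
  expect_setequal(got$end, want$end)
})

test_that("rescue recovers exactly the shared-segment multimappers", {
  fx <- two_pair_fixture(n_cells = 500, error_rate = 0,
                         pcr_duplication_mean = 1, seed = 47)
  rex <- rescue_experiment(fx$panels$refB, fx$reads, "IGHA1/IGHA2", "IGHA")

  # bookkeeping identity at error rate 0: merged-gene effective count
  # equals the plain-annotation discarded reads wholly inside the shared
  # segment (boundary 121 in transcript coordinates)
  plain <- rex$plain$assignments
  shared_truth <- grepl("^IGHA", fx$reads$true_gene) &
    fx$reads$true_offset >= 121
  expect_equal(rex$merged_assigned,
               sum(plain$class == "discarded_multimap" & shared_truth))
  expect_lte(rex$merged_effective, rex$merged_assigned)
  expect_gte(rex$effective_gain, 0)
  expect_true(rex$non_pair_unchanged)

  # rescue never changes a read that was uniquely assigned under plain
  resc <- rex$rescue$assignments
  was_assigned <- plain$class %in% c("effective", "pcr_duplicate")
  expect_equal(resc$assigned_gene[was_assigned],
               plain$assigned_gene[was_assigned])

  # per-cell IgA subclass percent drops while the family total rises
  wl <- fx$cells$barcode
  cmp <- quantify(plain, wl, features = c("IGHA1", "IGHA2", "IGHA"))
  cmr <- quantify(resc, wl, features = c("IGHA1", "IGHA2", "IGHA"))
  expect_equal(sum(cmp$counts["IGHA", ]), 0)
  expect_gt(sum(cmr$counts["IGHA", ]), 0)
  expect_equal(cmr$counts["IGHA1", ], cmp$counts["IGHA1", ])
  tot_p <- Matrix::colSums(cmp$counts); tot_r <- Matrix::colSums(cmr$counts)
  expect_true(all(tot_r >= tot_p))
  a_cells <- fx$cells$barcode[grepl("^IGHA", fx$cells$true_isotype)]
  rph_p <- 100 * cmp$counts["IGHA1", a_cells] / pmax(tot_p[a_cells], 1)
  rph_r <- 100 * cmr$counts["IGHA1", a_cells] / pmax(tot_r[a_cells], 1)
  expect_true(all(rph_r <= rph_p + 1e-9))
  expect_lt(mean(rph_r), mean(rph_p))

  # no shared region: reports identical
  sp0 <- pair_spec("P", "G1", "G2",
                   variants = data.frame(ref = "refB", pos = 300L,
                                         carrier = "gene1"))
  p0 <- build_allele_panel(list(sp0), seed = 48)
  cl0 <- simulate_cells(50, c(G1 = .5, G2 = .5), doublet_rate = 0,
                        seed = 49)
  rd0 <- simulate_reads(p0$refB, cl0, error_rate = 0,
                        pcr_duplication_mean = 1, seed = 50)
  rex0 <- rescue_experiment(p0$refB, rd0, c("G1", "G2"), "GM")
  expect_equal(rex0$plain$tally, rex0$rescue$tally)
  expect_equal(rex0$merged_effective, 0)
})

test_that("the rescue identity degrades gracefully with sequencing errors", {
  fx <- two_pair_fixture(n_cells = 400, error_rate = 0.001,
                         pcr_duplication_mean = 1, seed = 53)
  rex <- rescue_experiment(fx$panels$refB, fx$reads, "IGHA1/IGHA2", "IGHA")
  plain <- rex$plain$assignments
  shared_truth <- grepl("^IGHA", fx$reads$true_gene) &
    fx$reads$true_offset >= 121
  n_shared <- sum(plain$class == "discarded_multimap" & shared_truth)
  expect_lte(abs(rex$merged_assigned - n_shared),
             max(1, ceiling(0.01 * sum(shared_truth))))
})
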