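test_that("single-read alignment and assignment follow the tie policy", {
  pp <- build_allele_panel(list(ighg_swap_spec()), seed = 2)
  reg <- panel_regions(pp$refB)
  exon <- terminal_exon_seq(pp$refB, "IGHG2")

  # exact substring, one region: a single zero-mismatch placement wins
  read <- substr(exon, 40, 129)
  al <- align_read(read, reg[reg$gene_id == "IGHG2", ])
  expect_equal(al$mismatches[1], 0)
  expect_equal(al$offset[1], 40)

  # two regions differing at one covered base: best (0, 1), 0 wins
  read2 <- substr(exon, 150, 239)  # covers the 215/225/235 separators
  a2 <- assign_read(align_read(read2, reg))
  expect_equal(a2$class, "effective")
  expect_equal(a2$assigned_gene, "IGHG2")

  # identical windows in two genes: discarded as multi-mapping
  read3 <- substr(exon, 1, 90)   # upstream of every separating variant
  a3 <- assign_read(align_read(read3, reg))
  expect_equal(a3$class, "discarded_multimap")

  # ... but kept under the merged gene of a rescue annotation
  ppa <- build_allele_panel(list(igha_shared_tail_spec()), seed = 2)
  rreg <- rescue_regions(ppa$refB, "IGHA1/IGHA2", "IGHA")
  blue_read <- substr(terminal_exon_seq(ppa$refB, "IGHA1"), 150, 239)
  a4 <- assign_read(align_read(blue_read, rreg))
  expect_equal(a4$class, "effective")
  expect_equal(a4$assigned_gene, "IGHA")

  expect_error(align_read(read, reg[0, ]), "empty region set")
})

test_that("same-gene placement ties follow the rescue flag", {
  # a region with an internal 30-bp repeat: two same-gene placements
  unit <- "ACGTTGCAGGTCATGCAAGGTTCACGATGA"
  reg <- data.frame(region_id = "G1", gene_id = "G1",
                    seq = paste0(unit, unit), split_at = NA_integer_,
                    shared_gene = NA_character_)
  al <- align_read(unit, reg)
  expect_equal(nrow(al[al$mismatches == 0, ]), 2)
  a_on <- assign_read(al, assignment_policy(gene_level_rescue = TRUE))
  expect_equal(a_on$class, "effective")
  expect_equal(a_on$offset, 1)   # smallest offset kept
  a_off <- assign_read(al, assignment_policy(gene_level_rescue = FALSE))
  expect_equal(a_off$class, "discarded_multimap")
})

test_that("bulk assignment equals an independent brute-force scan", {
  fx <- two_pair_fixture(n_cells = 60, error_rate = 0.02, seed = 17)
  regions <- panel_regions(fx$panels$refA)
  set.seed(18)
  # mix of real reads (with errors) and pure noise
  noise <- replicate(100, paste(sample(c("A", "C", "G", "T"), 90, TRUE),
                                collapse = ""))
  reads <- data.frame(
    read_id = as.character(1:1000), barcode = "B", umi = "U",
    seq = c(sample(fx$reads$seq, 900), noise), stringsAsFactors = FALSE)
  pol <- assignment_policy()
  got <- assign_reads(reads, regions, pol)
  for (i in seq_len(nrow(reads))) {
    want <- oracle_assign(reads$seq[i], regions, pol$max_mismatch)
    expect_identical(got$class[i], want$class, info = paste("read", i))
    if (want$class == "effective") {
      expect_identical(got$assigned_gene[i], want$gene)
      expect_equal(got$mismatches[i], want$mismatches)
    }
  }
})

test_that("read classes are exhaustive and conserved", {
  fx <- two_pair_fixture(n_cells = 150, error_rate = 0.01,
                         pcr_duplication_mean = 1.6, seed = 23)
  for (ref in c("refA", "refB")) {
    for (rescue in c(TRUE, FALSE)) {
      a <- dedup_umis(assign_reads(fx$reads, panel_regions(fx$panels[[ref]]),
                                   assignment_policy(gene_level_rescue =
                                                       rescue)))
      tal <- class_tally(a)
      expect_equal(sum(tal$n), nrow(fx$reads))
      expect_true(all(xor(is.na(a$assigned_gene),
                          a$class %in% c("effective", "pcr_duplicate"))))
    }
  }
})

test_that("matched reference never misassigns error-free reads", {
  fx <- two_pair_fixture(n_cells = 300, error_rate = 0, seed = 29)
  a <- dedup_umis(assign_reads(fx$reads, panel_regions(fx$panels$refB)))
  asg <- a$class %in% c("effective", "pcr_duplicate")
  expect_true(all(a$assigned_gene[asg] == fx$reads$true_gene[asg]))
})

test_that("ancestry mismatch reproduces the mechanical misassignment", {
  # 3'-window reads of donor IGHG2 land on IGHG1 under the swapped panel
  pp <- build_allele_panel(list(ighg_swap_spec()), seed = 2)
  oc <- scan_window_outcomes(pp$refB, "IGHG2", panel_regions(pp$refA), 90)
  wrong <- oc$offset[oc$class == "effective" & oc$gene == "IGHG1"]
  expect_gt(length(wrong), 0)
  expect_true(all(wrong >= 181))       # the 3'-proximal window
  # and the same windows are assigned correctly under the matched panel
  ocB <- scan_window_outcomes(pp$refB, "IGHG2", panel_regions(pp$refB), 90)
  expect_true(all(ocB$gene[wrong] == "IGHG2"))
})

test_that("UMI deduplication keeps one effective read per molecule", {
  fx <- two_pair_fixture(n_cells = 40, error_rate = 0, seed = 31)
  a0 <- dedup_umis(assign_reads(fx$reads, panel_regions(fx$panels$refB)))
  expect_equal(sum(a0$class == "pcr_duplicate"), 0)  # duplication mean 1

  # k copies of one molecule: 1 effective + (k-1) duplicates
  keep1 <- which(a0$class == "effective")[1]
  one <- fx$reads[rep(keep1, 5), ]
  one$read_id <- paste0("r", 1:5)
  a1 <- dedup_umis(assign_reads(one, panel_regions(fx$panels$refB)))
  expect_equal(as.vector(table(a1$class)["effective"]), 1)
  expect_equal(sum(a1$class == "pcr_duplicate"), 4)

  # duplicate fraction matches the shifted-Poisson expectation at 1e4
  cells <- simulate_cells(100, c(IGHG1 = 1), doublet_rate = 0,
                          libsize_log_mean = log(100),
                          libsize_log_sd = 0.1, seed = 32)
  rd <- simulate_reads(fx$panels$refB, cells, error_rate = 0,
                       pcr_duplication_mean = 2, seed = 33)
  n_mol <- sum(cells$library_size)
  expect_gt(n_mol, 9000)
  a2 <- dedup_umis(assign_reads(rd, panel_regions(fx$panels$refB)))
  tal <- class_tally(a2)
  dup_frac <- tal$n[tal$class == "pcr_duplicate"] /
    sum(tal$n[tal$class %in% c("effective", "pcr_duplicate")])
  # expected fraction 1 - 1/mean_copies = 0.5; MC tolerance at ~2e4 reads
  expect_lt(abs(dup_frac - 0.5), 0.02)
})

test_that("quantification conserves classes and reflects reference bias", {
  fx <- two_pair_fixture(n_cells = 250, error_rate = 0, seed = 37)
  wl <- fx$cells$barcode
  eff_total <- c()
  for (ref in c("refA", "refB")) {
    a <- dedup_umis(assign_reads(fx$reads, panel_regions(fx$panels[[ref]])))
    cm <- quantify(a, wl)
    expect_equal(sum(cm$tallies$n), nrow(fx$reads))
    expect_equal(sum(cm$counts),
                 cm$tallies$n[cm$tallies$class == "effective"])
    igha <- grepl("^IGHA", rownames(cm$counts))
    eff_total[ref] <- sum(cm$counts[igha, ])
  }
  # the shared IgA tail multi-maps under the matched reference B:
  # fewer IGHA effective reads than under reference A
  expect_lt(eff_total["refB"], eff_total["refA"])

  # zero effective reads: all-zero matrix with full registries
  none <- data.frame(read_id = "r1", barcode = "X", umi = "U",
                     seq = strrep("A", 90))
  a0 <- assign_reads(none, panel_regions(fx$panels$refA))
  cm0 <- quantify(a0, whitelist = c("BC1", "BC2"),
                  features = c("IGHG1", "IGHG2"))
  expect_equal(dim(cm0$counts), c(2L, 2L))
  expect_equal(sum(cm0$counts), 0)
  expect_error(quantify(a0, character(0)), "whitelist")
})

test_that("count matrices survive the Matrix Market round-trip", {
  fx <- two_pair_fixture(n_cells = 50, error_rate = 0, seed = 41)
  a <- dedup_umis(assign_reads(fx$reads, panel_regions(fx$panels$refB)))
  cm <- quantify(a, fx$cells$barcode)
  dir <- withr::local_tempdir()
  write_count_matrix(cm, file.path(dir, "mtx"))
  cm2 <- read_count_matrix(file.path(dir, "mtx"))
  expect_equal(as.matrix(cm2$counts), as.matrix(cm$counts))
  expect_identical(cm2$barcodes, cm$barcodes)
  expect_identical(cm2$features, cm$features)
})
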