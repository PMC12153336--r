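## Mismatch-based read assignment ----------------------------------------
##
## A desk-scale model of the Cell Ranger / STAR behaviour the analysis
## diagnoses: every read is placed ungapped at every offset of every
## candidate gene region, assigned to the unique best-scoring gene,
## discarded when the best score is tied across genes (multi-mapping), and
## rescued when all tied placements point to one gene id.  Read classes
## mirror the BAM xf tag (effective / PCR duplicate / discarded), and the
## per-placement mismatch count and integer score mirror nM and AS.

#' Assignment policy
#'
#' @param max_mismatch Maximum mismatches for a placement to be retained
#'   (default 6 for 90-mers, a ~94\% identity floor).
#' @param gene_level_rescue Keep reads whose tied best placements all share
#'   one gene id (the Cell Ranger behaviour the rescue annotation relies
#'   on).  With `FALSE`, any tie among best placements discards the read.
#' @param match_bonus,mismatch_penalty Integer score weights:
#'   `score = match_bonus * (R - mismatches) - mismatch_penalty * mismatches`
#'   (monotone in mismatches, so score ranking equals mismatch ranking).
#' @return An `assignment_policy` list.
#' @export
assignment_policy <- function(max_mismatch = 6L, gene_level_rescue = TRUE,
                              match_bonus = 1L, mismatch_penalty = 2L) {
  structure(list(max_mismatch = as.integer(max_mismatch),
                 gene_level_rescue = isTRUE(gene_level_rescue),
                 match_bonus = as.integer(match_bonus),
                 mismatch_penalty = as.integer(mismatch_penalty)),
            class = "assignment_policy")
}

## Gene label of a placement: the shared (merged) gene when the window lies
## wholly inside the shared segment of a split exon, else the original gene.
placement_label <- function(regions, region_idx, offset) {
  lab <- regions$gene_id[region_idx]
  sh <- !is.na(regions$split_at[region_idx]) & !is.na(offset) &
    offset >= regions$split_at[region_idx]
  lab[sh] <- regions$shared_gene[region_idx][sh]
  lab
}

#' All retained placements of a single read
#'
#' Exhaustive ungapped scan of one read against every region and offset;
#' placements with more than `policy$max_mismatch` mismatches are dropped,
#' the rest are scored and sorted by (score desc, gene asc, offset asc).
#'
#' @param read_sequence Character scalar.
#' @param regions Region data frame ([panel_regions()] or
#'   [rescue_regions()]).
#' @param policy An [assignment_policy()].
#' @return A `CandidateAlignment` data frame: `gene_id`, `region_id`,
#'   `offset`, `mismatches`, `score`.
#' @export
align_read <- function(read_sequence, regions,
                       policy = assignment_policy()) {
  if (is.null(regions) || nrow(regions) == 0L) stop("empty region set")
  R <- nchar(read_sequence)
  out <- list()
  for (i in seq_len(nrow(regions))) {
    if (R > nchar(regions$seq[i])) next  # shorter region: skipped
    pl <- enumerate_placements_cpp(read_sequence, regions$seq[i],
                                   policy$max_mismatch)
    if (!length(pl$offset)) next
    out[[length(out) + 1L]] <- data.frame(
      gene_id = placement_label(regions, rep(i, length(pl$offset)),
                                pl$offset),
      region_id = regions$region_id[i], offset = pl$offset,
      mismatches = pl$mismatches, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), region_id = character(0),
                      offset = integer(0), mismatches = integer(0),
                      score = integer(0)))
  al <- do.call(rbind, out)
  al$score <- policy$match_bonus * (R - al$mismatches) -
    policy$mismatch_penalty * al$mismatches
  al[order(-al$score, al$gene_id, al$offset), , drop = FALSE]
}

#' Assign a single read from its candidate alignments
#'
#' No retained placement: unmapped.  Unique best-scoring gene label:
#' assigned (ties between equal-score placements of the same gene keep the
#' smallest offset).  Best score shared by two or more gene labels:
#' discarded as multi-mapping.  With `gene_level_rescue = FALSE` any tie
#' among best placements discards the read.
#'
#' @param alignments Output of [align_read()].
#' @param policy An [assignment_policy()].
#' @return One-row data frame: `class`, `assigned_gene`, `mismatches`,
#'   `offset`.
#' @export
assign_read <- function(alignments, policy = assignment_policy()) {
  if (nrow(alignments) == 0L)
    return(data.frame(class = "unmapped", assigned_gene = NA_character_,
                      mismatches = NA_integer_, offset = NA_integer_))
  best <- alignments[alignments$score == max(alignments$score), ,
                     drop = FALSE]
  genes <- unique(best$gene_id)
  if (length(genes) > 1L ||
      (!policy$gene_level_rescue && nrow(best) > 1L))
    return(data.frame(class = "discarded_multimap",
                      assigned_gene = NA_character_,
                      mismatches = NA_integer_, offset = NA_integer_))
  data.frame(class = "effective", assigned_gene = genes,
             mismatches = best$mismatches[1L], offset = min(best$offset))
}

#' Assign a whole read set (vectorised)
#'
#' Bulk equivalent of [align_read()] + [assign_read()] for every read,
#' using a compiled scan.  The result additionally records, for discarded
#' reads, the `+`-joined set of tied gene labels (`gene_set`), used for
#' gene-subset tallies.
#'
#' @param reads A `ReadSet` data frame (columns `read_id`, `barcode`,
#'   `umi`, `seq`).
#' @param regions Region data frame.
#' @param policy An [assignment_policy()].
#' @return An `AssignmentResult` data frame: `read_id`, `barcode`, `umi`,
#'   `class` (`effective` / `discarded_multimap` / `unmapped`; see
#'   [dedup_umis()] for `pcr_duplicate`), `assigned_gene`, `mismatches`,
#'   `offset`, `score`, `gene_set`.
#' @export
assign_reads <- function(reads, regions, policy = assignment_policy()) {
  if (is.null(regions) || nrow(regions) == 0L) stop("empty region set")
  n <- nrow(reads)
  ng <- nrow(regions)
  sc <- scan_regions_cpp(reads$seq, regions$seq, policy$max_mismatch)
  mm <- sc$mismatches; off <- sc$offset; cnt <- sc$n_best
  mmInf <- mm; mmInf[is.na(mmInf)] <- .Machine$integer.max
  best <- mmInf[, 1L]
  if (ng > 1L) for (g in 2:ng) best <- pmin(best, mmInf[, g])
  mapped <- best != .Machine$integer.max

  first <- rep(NA_character_, n)
  multi <- rep(FALSE, n)
  n_place <- rep(0L, n)
  best_off <- rep(NA_integer_, n)
  gene_set <- rep("", n)
  for (g in seq_len(ng)) {
    sel <- mapped & mmInf[, g] == best
    if (!any(sel)) next
    lab <- placement_label(regions, rep(g, n), off[, g])
    new <- sel & is.na(first)
    conflict <- sel & !is.na(first) & first != lab
    first[new] <- lab[new]
    multi[conflict] <- TRUE
    n_place[sel] <- n_place[sel] + cnt[sel, g]
    best_off[sel] <- pmin(best_off[sel], off[sel, g], na.rm = TRUE)
    gene_set[sel] <- ifelse(gene_set[sel] == "", lab[sel],
                            paste0(gene_set[sel], "+", lab[sel]))
  }
  discard <- mapped & (multi | (!policy$gene_level_rescue & n_place > 1L))
  assigned <- mapped & !discard

  cls <- rep("unmapped", n)
  cls[discard] <- "discarded_multimap"
  cls[assigned] <- "effective"
  R <- nchar(reads$seq)
  bestN <- ifelse(mapped, best, NA_integer_)
  out <- data.frame(
    read_id = reads$read_id, barcode = reads$barcode, umi = reads$umi,
    class = cls,
    assigned_gene = ifelse(assigned, first, NA_character_),
    mismatches = ifelse(assigned, bestN, NA_integer_),
    offset = ifelse(assigned, best_off, NA_integer_),
    score = policy$match_bonus * (R - bestN) -
      policy$mismatch_penalty * bestN,
    gene_set = ifelse(mapped, gene_set, NA_character_),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Flag PCR duplicates within (barcode, UMI, gene) groups
#'
#' Within each group of effective reads sharing barcode, UMI and assigned
#' gene, exactly one read (lowest mismatch count, then first seen) stays
#' `effective`; the others become `pcr_duplicate`.  Unmapped and discarded
#' reads are untouched.
#'
#' @param assignments An `AssignmentResult` data frame.
#' @return The same data frame with duplicate classes set.
#' @export
dedup_umis <- function(assignments) {
  idx <- which(assignments$class == "effective")
  if (!length(idx)) return(assignments)
  key <- paste(assignments$barcode[idx], assignments$umi[idx],
               assignments$assigned_gene[idx], sep = "\r")
  ord <- order(assignments$mismatches[idx], seq_along(idx))
  dup <- duplicated(key[ord])
  assignments$class[idx[ord][dup]] <- "pcr_duplicate"
  assignments
}

READ_CLASSES <- c("effective", "pcr_duplicate", "discarded_multimap",
                  "unmapped")

#' Per-class read tallies, optionally restricted to a gene subset
#'
#' @param assignments An `AssignmentResult` data frame.
#' @param gene_pattern Optional regex; assigned reads are matched on
#'   `assigned_gene`, discarded reads on their tied `gene_set` (a read tied
#'   between IGHA1 and IGHA2 belongs to the `"^IGHA"` subset).  Unmapped
#'   reads never match a pattern.
#' @return Data frame `class`, `n` over the four exhaustive classes.
#' @export
class_tally <- function(assignments, gene_pattern = NULL) {
  keep <- rep(TRUE, nrow(assignments))
  if (!is.null(gene_pattern)) {
    keep <- !is.na(assignments$gene_set) &
      grepl(gene_pattern, assignments$gene_set)
    keep[assignments$class %in% c("effective", "pcr_duplicate")] <-
      grepl(gene_pattern, assignments$assigned_gene[
        assignments$class %in% c("effective", "pcr_duplicate")])
  }
  tab <- table(factor(assignments$class[keep], levels = READ_CLASSES))
  data.frame(class = READ_CLASSES, n = as.integer(tab))
}

#' Build a cells-by-genes count matrix from effective reads
#'
#' Counts only `effective` reads of whitelisted barcodes; reads with
#' non-whitelist barcodes are tallied separately.  Feature metadata flags
#' mitochondrial, ribosomal, immunoglobulin and isotype genes by regex.
#'
#' @param assignments A deduplicated `AssignmentResult` data frame.
#' @param whitelist Non-empty character vector of barcodes (the registry;
#'   all appear as columns even at zero counts).
#' @param features Optional feature registry (rows); defaults to the
#'   assigned genes observed.
#' @param mito_pattern,ribo_pattern,ig_pattern,isotype_pattern Regexes for
#'   the feature flags.
#' @return A `CountMatrix`: list with sparse `counts` (features x
#'   barcodes), `features` data frame, `barcodes`, per-class `tallies` and
#'   `n_nonwhitelist`.
#' @export
quantify <- function(assignments, whitelist, features = NULL,
                     mito_pattern = "^MT-", ribo_pattern = "^RP[LS]",
                     ig_pattern = "^IG[HKL]",
                     isotype_pattern = "^IGH[MDEGA]") {
  if (!length(whitelist)) stop("whitelist must be non-empty")
  eff <- assignments[assignments$class == "effective", , drop = FALSE]
  inwl <- eff$barcode %in% whitelist
  if (is.null(features))
    features <- sort(unique(eff$assigned_gene[inwl]))
  features <- unique(features)
  fi <- factor(eff$assigned_gene[inwl], levels = features)
  bi <- factor(eff$barcode[inwl], levels = whitelist)
  ok <- !is.na(fi)
  counts <- Matrix::sparseMatrix(
    i = as.integer(fi[ok]), j = as.integer(bi[ok]), x = 1,
    dims = c(length(features), length(whitelist)),
    dimnames = list(features, whitelist))
  cm <- list(counts = methods::as(counts, "CsparseMatrix"),
             features = data.frame(
               feature_id = features,
               is_mito = grepl(mito_pattern, features),
               is_ribo = grepl(ribo_pattern, features),
               is_ig = grepl(ig_pattern, features),
               is_isotype = grepl(isotype_pattern, features),
               stringsAsFactors = FALSE),
             barcodes = whitelist,
             tallies = class_tally(assignments),
             n_nonwhitelist = sum(
               !(assignments$barcode %in% whitelist) &
                 assignments$class %in% c("effective", "pcr_duplicate")))
  structure(cm, class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix: ", nrow(x$counts), " features x ", ncol(x$counts),
      " barcodes, ", sum(x$counts), " effective counts\n", sep = "")
  print(x$tallies)
  invisible(x)
}

#' Stack additional feature rows onto a count matrix
#'
#' Used to add simulated background (mitochondrial / ribosomal /
#' housekeeping) counts so that QC and the antibody-secreting-cell rule
#' operate on realistic totals.
#'
#' @param cm A `CountMatrix`.
#' @param extra Sparse feature-by-barcode matrix over the same barcodes.
#' @return The extended `CountMatrix`.
#' @export
add_features <- function(cm, extra) {
  stopifnot(identical(colnames(extra), cm$barcodes))
  counts <- rbind(cm$counts, extra)
  feats <- rownames(counts)
  cm$counts <- counts
  cm$features <- data.frame(
    feature_id = feats,
    is_mito = grepl("^MT-", feats), is_ribo = grepl("^RP[LS]", feats),
    is_ig = grepl("^IG[HKL]", feats),
    is_isotype = grepl("^IGH[MDEGA]", feats), stringsAsFactors = FALSE)
  cm
}

#' Write a count matrix as a Matrix Market triple
#'
#' Cell Ranger layout: `matrix.mtx`, `barcodes.tsv`, `features.tsv`.
#'
#' @param cm A `CountMatrix`.
#' @param dir Output directory.
#' @param overwrite Logical.
#' @export
write_count_matrix <- function(cm, dir, overwrite = FALSE) {
  check_outdir(dir, overwrite, pattern = "matrix\\.mtx")
  Matrix::writeMM(cm$counts, file.path(dir, "matrix.mtx"))
  writeLines(cm$barcodes, file.path(dir, "barcodes.tsv"))
  write.table(cm$features, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a Matrix Market triple back into a `CountMatrix`
#' @param dir Directory written by [write_count_matrix()].
#' @return A `CountMatrix` (tallies empty).
#' @export
read_count_matrix <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  feats <- read.delim(file.path(dir, "features.tsv"), header = FALSE,
                      colClasses = c("character", rep("logical", 4L)))
  names(feats) <- c("feature_id", "is_mito", "is_ribo", "is_ig",
                    "is_isotype")
  dimnames(counts) <- list(feats$feature_id, barcodes)
  structure(list(counts = counts, features = feats, barcodes = barcodes,
                 tallies = data.frame(class = READ_CLASSES,
                                      n = NA_integer_),
                 n_nonwhitelist = NA_integer_), class = "CountMatrix")
}
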