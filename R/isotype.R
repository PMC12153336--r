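## Cell-level pipeline: QC, ASC selection, isotype calling, DP detection --

#' Quality-control parameters
#'
#' Defaults follow the standard droplet scRNA-seq practice for plasma-cell
#' data: cells over 10\% mitochondrial expression removed; ribosomal genes
#' removed; genes expressed in under 0.5\% of cells removed (0.25\% for
#' sparser tissues); cells under 1500 reads or 450 detected genes removed;
#' and only cells over 10\% immunoglobulin expression count as
#' antibody-secreting cells (ASCs).
#'
#' @param max_mito_fraction Maximum mitochondrial count fraction.
#' @param min_reads,min_genes Per-cell minima applied after gene filtering.
#' @param min_gene_prevalence Minimum fraction of cells expressing a gene.
#' @param drop_ribosomal Remove ribosomal genes at step (ii).
#' @param min_ig_fraction_for_asc ASC rule threshold.
#' @return A `qc_params` list.
#' @export
qc_params <- function(max_mito_fraction = 0.10, min_reads = 1500L,
                      min_genes = 450L, min_gene_prevalence = 0.005,
                      drop_ribosomal = TRUE,
                      min_ig_fraction_for_asc = 0.10) {
  stopifnot(max_mito_fraction >= 0, max_mito_fraction <= 1,
            min_gene_prevalence >= 0, min_gene_prevalence <= 1,
            min_reads >= 0, min_genes >= 0)
  structure(list(max_mito_fraction = max_mito_fraction,
                 min_reads = min_reads, min_genes = min_genes,
                 min_gene_prevalence = min_gene_prevalence,
                 drop_ribosomal = isTRUE(drop_ribosomal),
                 min_ig_fraction_for_asc = min_ig_fraction_for_asc),
            class = "qc_params")
}

#' Four-step quality-control filter
#'
#' Applies, in this order (the steps do not commute): (i) drop cells whose
#' mitochondrial fraction exceeds the maximum; (ii) drop ribosomal genes;
#' (iii) drop genes expressed in fewer than `min_gene_prevalence` of the
#' remaining cells; (iv) drop cells with fewer than `min_reads` reads or
#' `min_genes` detected genes.
#'
#' @param cm A `CountMatrix` with mito/ribo feature flags.
#' @param params A [qc_params()] list.
#' @return List: `matrix` (filtered `CountMatrix`) and `report` (one row
#'   per step: cells/genes removed and remaining, in application order).
#' @export
qc_filter <- function(cm, params = qc_params()) {
  m <- cm$counts
  feats <- cm$features
  report <- list()
  note <- function(step, removed, what) {
    report[[length(report) + 1L]] <<- data.frame(
      step = step, removed = removed, unit = what,
      cells_remaining = ncol(m), genes_remaining = nrow(m))
  }
  ## (i) mito fraction
  if (params$max_mito_fraction < 1) {
    if (is.null(feats$is_mito) || !any(feats$is_mito))
      stop("matrix lacks mitochondrial feature annotation")
    tot <- Matrix::colSums(m)
    mito <- Matrix::colSums(m[feats$is_mito, , drop = FALSE])
    keep <- tot == 0 | mito / pmax(tot, 1) <= params$max_mito_fraction
    m <- m[, keep, drop = FALSE]
    note("mito_fraction", sum(!keep), "cells")
  } else note("mito_fraction", 0L, "cells")
  ## (ii) ribosomal genes
  keepg <- if (params$drop_ribosomal) !feats$is_ribo else
    rep(TRUE, nrow(feats))
  m <- m[keepg, , drop = FALSE]
  feats <- feats[keepg, , drop = FALSE]
  note("ribosomal_genes", sum(!keepg), "genes")
  ## (iii) gene prevalence
  prev <- Matrix::rowSums(m > 0) / max(1L, ncol(m))
  keepg <- prev >= params$min_gene_prevalence
  m <- m[keepg, , drop = FALSE]
  feats <- feats[keepg, , drop = FALSE]
  note("gene_prevalence", sum(!keepg), "genes")
  ## (iv) per-cell depth
  keep <- Matrix::colSums(m) >= params$min_reads &
    Matrix::colSums(m > 0) >= params$min_genes
  m <- m[, keep, drop = FALSE]
  note("cell_depth", sum(!keep), "cells")

  out <- cm
  out$counts <- m
  out$features <- feats
  out$barcodes <- colnames(m)
  rep <- do.call(rbind, report)
  rep$order <- seq_len(nrow(rep))
  list(matrix = out, report = rep)
}

#' Select antibody-secreting cells
#'
#' Cells whose immunoglobulin-gene count fraction exceeds the threshold.
#' When a second matrix is given (the other reference's output), the
#' intersection of ASC barcodes passing in both is returned, mirroring the
#' requirement that cells appear in both outputs.
#'
#' @param cm A `CountMatrix`.
#' @param ig_pattern Regex for immunoglobulin features.
#' @param min_ig_fraction Threshold (default 0.10).
#' @param other Optional second `CountMatrix` for intersection mode.
#' @return Character vector of ASC barcodes.
#' @export
select_ascs <- function(cm, ig_pattern = "^IG[HKL]", min_ig_fraction = 0.10,
                        other = NULL) {
  ig <- grepl(ig_pattern, cm$features$feature_id)
  if (!any(ig)) stop("no features match ig_pattern")
  tot <- Matrix::colSums(cm$counts)
  igc <- Matrix::colSums(cm$counts[ig, , drop = FALSE])
  asc <- cm$barcodes[tot > 0 & igc / pmax(tot, 1) > min_ig_fraction]
  if (!is.null(other))
    asc <- intersect(asc, select_ascs(other, ig_pattern, min_ig_fraction))
  asc
}

#' Normalised expression value
#'
#' `log1p(y / L * scale)` -- the log1p-of-reads-per-10,000 display
#' transform -- or, with `type = "rph"`, reads per hundred (`100 * y / L`)
#' without the log.
#'
#' @param y Gene read count(s).
#' @param L Cell total read count(s), positive.
#' @param scale Scale for the log form (1e4 by default).
#' @param type `"log1p"` or `"rph"`.
#' @return Numeric vector.
#' @export
expression_value <- function(y, L, scale = 1e4, type = c("log1p", "rph")) {
  type <- match.arg(type)
  if (any(L <= 0)) stop("undefined expression for a cell with L = 0")
  if (any(y < 0 | y > L)) stop("y must lie in [0, L]")
  if (type == "rph") 100 * y / L else log1p(y / L * scale)
}

#' Call one isotype per cell
#'
#' Per-cell fractions over the isotype gene set; a cell is called as the
#' isotype accounting for more than `call_threshold` (default 85\%) of its
#' total isotype expression, else `unassigned`.  Cells with zero isotype
#' counts get all-zero fractions and `unassigned`.
#'
#' @param cm A `CountMatrix`.
#' @param isotype_genes Optional character vector; defaults to features
#'   flagged `is_isotype`.
#' @param call_threshold Fraction threshold.
#' @return An `IsotypeCallTable` data frame: `barcode`, `library_size`
#'   (total cell counts), one `frac_<gene>` column per isotype, `call`.
#' @export
call_isotypes <- function(cm, isotype_genes = NULL, call_threshold = 0.85) {
  if (is.null(isotype_genes))
    isotype_genes <- cm$features$feature_id[cm$features$is_isotype]
  isotype_genes <- intersect(isotype_genes, cm$features$feature_id)
  if (!length(isotype_genes)) stop("no isotype genes present in matrix")
  sub <- cm$counts[isotype_genes, , drop = FALSE]
  tot <- Matrix::colSums(sub)
  frac <- t(as.matrix(sub)) / pmax(tot, 1)
  frac[tot == 0, ] <- 0
  call <- rep("unassigned", ncol(cm$counts))
  mx <- apply(frac, 1L, max)
  wx <- isotype_genes[apply(frac, 1L, which.max)]
  call[mx > call_threshold] <- wx[mx > call_threshold]
  out <- data.frame(barcode = cm$barcodes,
                    library_size = Matrix::colSums(cm$counts),
                    stringsAsFactors = FALSE)
  colnames(frac) <- paste0("frac_", isotype_genes)
  out <- cbind(out, as.data.frame(frac, row.names = NULL))
  out$call <- call
  structure(out, isotype_genes = isotype_genes,
            call_threshold = call_threshold,
            class = c("IsotypeCallTable", "data.frame"))
}

#' Detect double-positive (DP) cells for a gene pair
#'
#' A cell is DP for (g1, g2) when its percent-of-total counts exceed the
#' pair thresholds for both genes simultaneously -- genuine only for
#' doublets under the one-cell-one-antibody principle, so an excess of DP
#' cells over the doublet rate diagnoses reference-driven misassignment.
#'
#' @param cm A `CountMatrix`.
#' @param pair Character vector of two gene ids.
#' @param thresholds Percent thresholds `c(t1, t2)` (e.g. `c(0.5, 0.5)` for
#'   IGHG1/IGHG2, `c(0.8, 0.3)` for IGHA1/IGHA2).
#' @return List: `dp` (named logical per barcode), `n_dp`, `percent` (the
#'   two per-cell percent vectors, for scatter-plot export).
#' @export
detect_dp <- function(cm, pair, thresholds) {
  stopifnot(length(pair) == 2L, length(thresholds) == 2L,
            all(thresholds > 0))
  miss <- setdiff(pair, cm$features$feature_id)
  if (length(miss)) stop("pair gene(s) missing: ", paste(miss,
                                                         collapse = ", "))
  L <- Matrix::colSums(cm$counts)
  p1 <- 100 * cm$counts[pair[1L], ] / pmax(L, 1)
  p2 <- 100 * cm$counts[pair[2L], ] / pmax(L, 1)
  dp <- p1 > thresholds[1L] & p2 > thresholds[2L]
  names(dp) <- cm$barcodes
  list(dp = dp, n_dp = sum(dp),
       percent = data.frame(barcode = cm$barcodes, percent_1 = as.numeric(p1),
                            percent_2 = as.numeric(p2)))
}

## ---- rank-sum machinery (in-repo, permutation-guarded) ------------------

#' Two-sided rank-sum test (tie-corrected normal approximation)
#'
#' Wilcoxon-Mann-Whitney on two samples using the normal approximation
#' with tie correction and continuity correction.
#'
#' @param x,y Numeric samples.
#' @return List: `statistic` (Mann-Whitney U for `x`), `p_value`,
#'   `direction` (sign of the location shift of `x` relative to `y`).
#' @export
rank_sum_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  z <- U - mu
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
  list(statistic = U, p_value = min(1, 2 * pnorm(-abs(z))),
       direction = sign(U - mu))
}

#' Permutation rank-sum test
#'
#' Exact when all splits can be enumerated (`choose(n, n1) <=
#' max_enumeration`), otherwise a seeded Monte-Carlo permutation test.
#' Two-sided on the rank-sum statistic.
#'
#' @param x,y Numeric samples.
#' @param max_enumeration Enumeration cap.
#' @param n_perm Monte-Carlo permutations when enumeration is infeasible.
#' @param seed Seed for the Monte-Carlo branch.
#' @return List: `p_value`, `exact` (logical).
#' @export
perm_rank_sum_test <- function(x, y, max_enumeration = 2e5, n_perm = 4e4,
                               seed = 1L) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  s_obs <- sum(r[seq_len(n1)])
  dev_obs <- abs(s_obs - n1 * (n + 1) / 2)
  if (choose(n, n1) <= max_enumeration) {
    splits <- combn(n, n1)
    s <- colSums(matrix(r[splits], nrow = n1))
    p <- mean(abs(s - n1 * (n + 1) / 2) >= dev_obs - 1e-9)
    return(list(p_value = p, exact = TRUE))
  }
  set.seed(seed)
  s <- vapply(seq_len(n_perm), function(i) sum(r[sample.int(n, n1)]), 0)
  p <- (1 + sum(abs(s - n1 * (n + 1) / 2) >= dev_obs - 1e-9)) / (n_perm + 1)
  list(p_value = p, exact = FALSE)
}

#' Library-size doublet diagnostic
#'
#' Two-sided rank-sum comparison of library sizes between DP and non-DP
#' cells: genuine doublets carry roughly twice the reads of singlets, so a
#' significant upward shift supports the doublet interpretation of the DP
#' cells, while a null result indicates they are ordinary cells made DP by
#' misassigned reads.  Uses the permutation test when the smaller group has
#' at most 20 cells, the tie-corrected normal approximation otherwise (or
#' force either via `method`).
#'
#' @param dp Logical vector (TRUE = DP cell).
#' @param library_sizes Numeric vector aligned with `dp`.
#' @param method `"auto"`, `"normal"` or `"permutation"`.
#' @param seed Seed for the Monte-Carlo permutation branch.
#' @return List: `statistic`, `p_value`, `method`, `direction`,
#'   `median_dp`, `median_other`, `n_dp`, `n_other`; or a `skipped` notice
#'   when either group is empty.
#' @export
doublet_diagnostic <- function(dp, library_sizes,
                               method = c("auto", "normal", "permutation"),
                               seed = 1L) {
  method <- match.arg(method)
  x <- library_sizes[dp]
  y <- library_sizes[!dp]
  if (!length(x) || !length(y))
    return(list(skipped = TRUE,
                notice = "empty group: doublet diagnostic not run"))
  if (method == "auto")
    method <- if (min(length(x), length(y)) <= 20L) "permutation" else
      "normal"
  ns <- rank_sum_test(x, y)
  p <- if (method == "permutation")
    perm_rank_sum_test(x, y, seed = seed)$p_value else ns$p_value
  list(statistic = ns$statistic, p_value = p, method = method,
       direction = ns$direction, median_dp = median(x),
       median_other = median(y), n_dp = length(x), n_other = length(y),
       skipped = FALSE)
}
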