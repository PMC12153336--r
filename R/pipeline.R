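## End-to-end experiment orchestration ------------------------------------

#' Experiment configuration
#'
#' Validated container for a full simulate -> map (under both references)
#' -> quantify -> QC -> call -> DP/doublet-report experiment.  Every random
#' stage derives its own seed from the master `seed`.
#'
#' @param specs List of [pair_spec()] objects (the allele-panel design).
#' @param singletons Optional [singleton_spec()] list.
#' @param base_exon_length,utr_length,ref_names Panel geometry.
#' @param donor_ref Reference whose alleles the donor carries (the
#'   ancestry-matched reference).
#' @param n_cells,isotype_proportions,doublet_rate Cell population.
#' @param libsize_log_mean,libsize_log_sd Library-size law.
#' @param background_fraction Background share of each cell's counts (0
#'   disables background genes, mito QC and the prevalence filter are then
#'   moot).
#' @param read_length,error_rate,position_bias,bias_rate,pcr_duplication_mean
#'   Read simulation.
#' @param policy An [assignment_policy()].
#' @param qc A [qc_params()] list, or `NULL` to skip QC.
#' @param call_threshold Isotype call threshold.
#' @param dp_pairs List of `list(pair = c(g1, g2), thresholds = c(t1, t2))`.
#' @param rescue `NULL`, or `list(ref, pair, merged_gene_id)` to add a
#'   rescue-annotation output for one reference.
#' @param seed Master seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(specs, singletons = list(),
                              base_exon_length = 300L, utr_length = 120L,
                              ref_names = c("refA", "refB"),
                              donor_ref = "refB", n_cells = 2000L,
                              isotype_proportions, doublet_rate = 0.02,
                              libsize_log_mean = log(80),
                              libsize_log_sd = 0.5,
                              background_fraction = 0.4,
                              read_length = 90L, error_rate = 0.005,
                              position_bias = "3prime-geometric",
                              bias_rate = 0.03, pcr_duplication_mean = 1.5,
                              policy = assignment_policy(),
                              qc = NULL, call_threshold = 0.85,
                              dp_pairs = list(), rescue = NULL,
                              seed = 1L) {
  stopifnot(donor_ref %in% ref_names,
            abs(sum(isotype_proportions) - 1) < 1e-9,
            doublet_rate >= 0, doublet_rate <= 0.5,
            read_length <= base_exon_length, pcr_duplication_mean >= 1)
  if (!is.null(rescue))
    stopifnot(all(c("ref", "pair", "merged_gene_id") %in% names(rescue)),
              rescue$ref %in% ref_names)
  cfg <- as.list(environment())
  structure(cfg, class = "experiment_config")
}

#' Load an experiment configuration from YAML
#'
#' Scalar fields mirror the [experiment_config()] arguments; `specs` may
#' name a shipped configuration (`"ighg_swap"`, `"igha_shared_tail"`) or
#' spell out pair specs as lists.
#'
#' @param path YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.character(y$specs)) {
    y$specs <- lapply(y$specs, function(nm)
      switch(nm, ighg_swap = ighg_swap_spec(),
             igha_shared_tail = igha_shared_tail_spec(),
             stop("unknown shipped spec: ", nm)))
  } else {
    y$specs <- lapply(y$specs, function(s)
      pair_spec(s$pair_id, s$gene1, s$gene2,
                variants = as.data.frame(lapply(s$variants, unlist)),
                strand = s$strand %||% "-"))
  }
  if (!is.null(y$policy)) y$policy <- do.call(assignment_policy, y$policy)
  if (!is.null(y$qc)) y$qc <- do.call(qc_params, y$qc)
  y$isotype_proportions <- unlist(y$isotype_proportions)
  y$dp_pairs <- lapply(y$dp_pairs, function(d)
    list(pair = unlist(d$pair), thresholds = unlist(d$thresholds)))
  if (!is.null(y$rescue)) y$rescue$pair <- unlist(y$rescue$pair)
  do.call(experiment_config, y)
}

subset_cells <- function(cm, barcodes) {
  cm$counts <- cm$counts[, barcodes, drop = FALSE]
  cm$barcodes <- barcodes
  cm
}

#' Run a full experiment under both references
#'
#' Simulates cells and reads from the donor alleles, maps and quantifies
#' them under each reference (plus, optionally, under a rescue annotation
#' of one reference), applies QC, selects the ASCs appearing in every
#' output, calls isotypes, detects DP cells for the configured pairs and
#' runs the library-size doublet diagnostic.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory: writes count matrices (Matrix Market
#'   triple), call tables, DP summaries and the summary JSON.
#' @return A `bundle` list: `config`, `panels`, `cells`, `reads`, per-
#'   output `refs` (each with `assignments`, `cm_raw`, `cm`, `qc_report`,
#'   `calls`, `dp`, `asc`), `asc` (shared barcodes) and `summary`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  panels <- build_allele_panel(config$specs,
                               base_exon_length = config$base_exon_length,
                               utr_length = config$utr_length,
                               seed = derive_seed(config$seed, 1L),
                               ref_names = config$ref_names,
                               singletons = config$singletons)
  cells <- simulate_cells(config$n_cells, config$isotype_proportions,
                          doublet_rate = config$doublet_rate,
                          libsize_log_mean = config$libsize_log_mean,
                          libsize_log_sd = config$libsize_log_sd,
                          background_fraction = config$background_fraction,
                          seed = derive_seed(config$seed, 2L))
  reads <- simulate_reads(panels[[config$donor_ref]], cells,
                          read_length = config$read_length,
                          error_rate = config$error_rate,
                          position_bias = config$position_bias,
                          bias_rate = config$bias_rate,
                          pcr_duplication_mean = config$pcr_duplication_mean,
                          seed = derive_seed(config$seed, 3L))

  region_sets <- lapply(panels, panel_regions)
  names(region_sets) <- config$ref_names
  if (!is.null(config$rescue)) {
    region_sets[[paste0(config$rescue$ref, "_rescue")]] <-
      rescue_regions(panels[[config$rescue$ref]], config$rescue$pair,
                     config$rescue$merged_gene_id)
  }

  iso_features <- unique(c(unlist(lapply(region_sets, function(r)
    unique(c(r$gene_id, r$shared_gene))))))
  iso_features <- iso_features[!is.na(iso_features)]

  refs <- lapply(names(region_sets), function(r) {
    a <- dedup_umis(assign_reads(reads, region_sets[[r]], config$policy))
    eff <- a[a$class == "effective", , drop = FALSE]
    cm <- quantify(a, whitelist = cells$barcode,
                   features = intersect(iso_features,
                                        c(region_sets[[r]]$gene_id,
                                          region_sets[[r]]$shared_gene)))
    if (config$background_fraction > 0) {
      ## scaled against the true molecule counts so the background block is
      ## identical across references (a cell's transcriptome does not
      ## depend on the reference it is mapped to)
      bg <- simulate_background_counts(
        cells, setNames(cells$library_size, cells$barcode),
        seed = derive_seed(config$seed, 4L))
      cm <- add_features(cm, bg)
    }
    qc_report <- NULL
    cmf <- cm
    if (!is.null(config$qc)) {
      q <- qc_filter(cm, config$qc)
      cmf <- q$matrix
      qc_report <- q$report
    }
    list(name = r, assignments = a, cm_raw = cm, cm = cmf,
         qc_report = qc_report, tally = class_tally(a))
  })
  names(refs) <- names(region_sets)

  ## ASCs: cells passing the Ig rule in every output.
  asc <- Reduce(intersect, lapply(refs, function(b)
    select_ascs(b$cm, min_ig_fraction =
                  (config$qc %||% qc_params())$min_ig_fraction_for_asc)))
  if (!length(asc)) stop("stage asc_selection: no shared ASC barcodes")

  for (r in names(refs)) {
    cma <- subset_cells(refs[[r]]$cm, asc)
    refs[[r]]$asc_cm <- cma
    refs[[r]]$calls <- call_isotypes(cma,
                                     call_threshold = config$call_threshold)
    refs[[r]]$dp <- lapply(config$dp_pairs, function(dpp) {
      if (!all(dpp$pair %in% cma$features$feature_id))
        return(list(pair = dpp$pair, n_dp = NA_integer_, skipped = TRUE))
      d <- detect_dp(cma, dpp$pair, dpp$thresholds)
      diag <- doublet_diagnostic(d$dp, Matrix::colSums(cma$counts),
                                 seed = derive_seed(config$seed, 5L))
      list(pair = dpp$pair, thresholds = dpp$thresholds, dp = d$dp,
           n_dp = d$n_dp, rate = d$n_dp / length(asc),
           percent = d$percent, diagnostic = diag, skipped = FALSE)
    })
  }

  bundle <- list(config = config, panels = panels, cells = cells,
                 reads = reads, refs = refs, asc = asc)
  bundle$summary <- summarise_bundle(bundle)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  structure(bundle, class = "experiment_bundle")
}

summarise_bundle <- function(bundle) {
  refs <- lapply(bundle$refs, function(b) {
    tal <- setNames(as.list(b$tally$n), b$tally$class)
    dps <- lapply(b$dp, function(d)
      if (isTRUE(d$skipped)) list(pair = paste(d$pair, collapse = "/"),
                                  skipped = TRUE)
      else list(pair = paste(d$pair, collapse = "/"), n_dp = d$n_dp,
                rate = d$rate,
                doublet_p = if (isTRUE(d$diagnostic$skipped)) NULL else
                  d$diagnostic$p_value))
    calls <- sort(table(b$calls$call), decreasing = TRUE)
    list(tallies = tal, n_asc = nrow(b$calls),
         calls = setNames(as.list(as.integer(calls)), names(calls)),
         dp = dps)
  })
  list(schema = "isoref-summary/1", n_cells = nrow(bundle$cells),
       n_doublets = sum(bundle$cells$is_doublet),
       n_reads = nrow(bundle$reads), n_asc = length(bundle$asc),
       refs = refs)
}

write_bundle <- function(bundle, out_dir) {
  check_outdir(out_dir, overwrite = TRUE)
  for (r in names(bundle$refs)) {
    b <- bundle$refs[[r]]
    write_count_matrix(b$cm, file.path(out_dir, r), overwrite = TRUE)
    write.table(as.data.frame(b$calls),
                file.path(out_dir, paste0(r, "_calls.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(b$tally, file.path(out_dir, paste0(r, "_tally.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (i in seq_along(b$dp)) {
      d <- b$dp[[i]]
      if (!isTRUE(d$skipped))
        write.table(d$percent,
                    file.path(out_dir, sprintf("%s_dp_%s.tsv", r,
                                               paste(d$pair,
                                                     collapse = "_"))),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  jsonlite::write_json(bundle$summary,
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Compare two reference outputs cell-by-cell and gene-by-gene
#'
#' Pairs per-cell totals, detected gene counts and per-gene
#' percent-of-total values across the shared barcodes of two outputs, with
#' Pearson and Spearman summaries -- the scatter-plot data behind
#' cross-reference comparisons.
#'
#' @param bundleA,bundleB Elements of `run_experiment()$refs` (each needs
#'   `asc_cm`), or `CountMatrix` objects.
#' @return List: `per_cell` (barcode, reads and genes detected under A and
#'   B), `per_gene_percent` (per shared gene and barcode), `correlations`.
#' @export
compare_outputs <- function(bundleA, bundleB) {
  cma <- if (inherits(bundleA, "CountMatrix")) bundleA else bundleA$asc_cm
  cmb <- if (inherits(bundleB, "CountMatrix")) bundleB else bundleB$asc_cm
  shared <- intersect(cma$barcodes, cmb$barcodes)
  if (!length(shared)) stop("empty barcode intersection")
  ca <- cma$counts[, shared, drop = FALSE]
  cb <- cmb$counts[, shared, drop = FALSE]
  per_cell <- data.frame(
    barcode = shared,
    reads_A = as.numeric(Matrix::colSums(ca)),
    reads_B = as.numeric(Matrix::colSums(cb)),
    genes_A = as.numeric(Matrix::colSums(ca > 0)),
    genes_B = as.numeric(Matrix::colSums(cb > 0)))
  genes <- intersect(rownames(ca), rownames(cb))
  pg <- do.call(rbind, lapply(genes, function(g) data.frame(
    gene = g, barcode = shared,
    percent_A = as.numeric(100 * ca[g, ] / pmax(Matrix::colSums(ca), 1)),
    percent_B = as.numeric(100 * cb[g, ] / pmax(Matrix::colSums(cb), 1)))))
  corr <- function(x, y) {
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(c(pearson = NA_real_, spearman = NA_real_))
    c(pearson = cor(x, y), spearman = cor(x, y, method = "spearman"))
  }
  cors <- rbind(
    data.frame(quantity = "reads_per_cell",
               t(corr(per_cell$reads_A, per_cell$reads_B))),
    data.frame(quantity = "genes_per_cell",
               t(corr(per_cell$genes_A, per_cell$genes_B))),
    do.call(rbind, lapply(genes, function(g) {
      s <- pg[pg$gene == g, ]
      data.frame(quantity = paste0("percent_", g),
                 t(corr(s$percent_A, s$percent_B)))
    })))
  list(per_cell = per_cell, per_gene_percent = pg, correlations = cors)
}
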