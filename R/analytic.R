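## Analytic expectations for the misassignment artifact -------------------

#' Per-offset assignment outcome of error-free windows
#'
#' For every valid start offset of a donor gene's terminal exon, computes
#' how an error-free read starting there is classified against a reference
#' region set -- the mechanical core of the artifact: under an
#' ancestry-mismatched reference some windows are assigned to the wrong
#' paralog, others are discarded as multi-mapping.
#'
#' @param donor_panel Donor `AllelePanel`.
#' @param donor_gene Gene the molecules originate from.
#' @param regions Reference region set ([panel_regions()] /
#'   [rescue_regions()]).
#' @param read_length Window length.
#' @param policy An [assignment_policy()].
#' @return Data frame `offset`, `class`, `gene` (NA unless assigned).
#' @export
scan_window_outcomes <- function(donor_panel, donor_gene, regions,
                                 read_length,
                                 policy = assignment_policy()) {
  exon <- terminal_exon_seq(donor_panel, donor_gene)
  n_off <- nchar(exon) - read_length + 1L
  if (n_off < 1L) stop("read_length exceeds exon length")
  starts <- seq_len(n_off)
  win <- data.frame(read_id = as.character(starts), barcode = "NA",
                    umi = "NA",
                    seq = substring(exon, starts, starts + read_length - 1L),
                    stringsAsFactors = FALSE)
  a <- assign_reads(win, regions, policy)
  data.frame(offset = starts, class = a$class, gene = a$assigned_gene,
             stringsAsFactors = FALSE)
}

## Per-label window probabilities for one donor gene under one reference.
outcome_probs <- function(outcomes, weights, labels) {
  p <- vapply(labels, function(l)
    sum(weights[outcomes$class == "effective" & !is.na(outcomes$gene) &
                  outcomes$gene == l]), 0)
  c(p, dropped = 1 - sum(p))
}

#' Expected double-positive rate among singlets from interval lengths
#'
#' Closed-form expectation of the DP rate that the read-misassignment
#' artifact produces, computed from the per-offset window outcomes (which
#' derive from the region decomposition of the paralog pair) and the read
#' start-position distribution -- no reads are simulated.  For a singlet
#' with n molecules of gene g, the number assigned to each paralog is
#' multinomial over the window-outcome probabilities; the cell is DP when
#' both paralogs exceed their percent thresholds of the cell's effective
#' total.  Doublets are excluded: their DP status reflects genuine
#' co-occurrence, not the artifact.
#'
#' @param donor_panel Donor panel.
#' @param regions Reference region set.
#' @param cells `CellTruthTable`.
#' @param pair Character vector of the two gene ids tested for DP.
#' @param thresholds Percent-of-total thresholds `c(t1, t2)`.
#' @param read_length,position_bias,bias_rate Read geometry (must match the
#'   simulation being predicted).
#' @param policy An [assignment_policy()].
#' @return List: `rate` (expected singlet DP rate), `per_gene_probs`
#'   (window-outcome probabilities per donor gene).
#' @export
expected_dp_rate <- function(donor_panel, regions, cells, pair, thresholds,
                             read_length = 90L,
                             position_bias = "3prime-geometric",
                             bias_rate = 0.03,
                             policy = assignment_policy()) {
  singlets <- cells[!cells$is_doublet, , drop = FALSE]
  genes <- unique(singlets$true_isotype)
  probs <- lapply(setNames(genes, genes), function(g) {
    oc <- scan_window_outcomes(donor_panel, g, regions, read_length, policy)
    w <- offset_weights(nrow(oc), position_bias, bias_rate)
    outcome_probs(oc, w, pair)
  })
  ## P(DP) for one cell: m assigned ~ Bin(n, p1+p2), X1|m ~ Bin(m, p1/(p1+p2));
  ## DP iff X1/m > t1/100 and (m-X1)/m > t2/100 (strict, as in the caller).
  p_dp_one <- function(n, p1, p2, t1, t2) {
    pa <- p1 + p2
    if (pa == 0) return(0)
    r <- p1 / pa
    m <- 0:n
    dm <- stats::dbinom(m, n, pa)
    xmin <- floor(t1 / 100 * m + 1e-9) + 1
    xmax <- ceiling(m - t2 / 100 * m - 1e-9) - 1
    pin <- ifelse(xmax >= xmin,
                  stats::pbinom(xmax, m, r) -
                    stats::pbinom(xmin - 1, m, r), 0)
    sum(dm * pin)
  }
  key <- paste(singlets$true_isotype, singlets$library_size)
  uk <- !duplicated(key)
  pk <- vapply(which(uk), function(i) {
    pr <- probs[[singlets$true_isotype[i]]]
    p_dp_one(singlets$library_size[i], pr[[pair[1L]]], pr[[pair[2L]]],
             thresholds[1L], thresholds[2L])
  }, 0)
  names(pk) <- key[uk]
  list(rate = mean(pk[key]), per_gene_probs = probs)
}
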