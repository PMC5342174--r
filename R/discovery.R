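# Biomarker discovery: detection frequencies, Wilcoxon screening with BH
# correction, the frequency/significance panel filter, and the signed
# differential-excretion ratio.

#' Per-peptide detection frequencies by group
#'
#' Frequency is the fraction of samples in a group with amplitude > 0.
#' @param matrix amplitude matrix (samples x peptides, 0 = undetected)
#' @param labels case/control labels covering all rows
#' @return data.frame (peptide_id, freq_case, freq_control)
#' @export
detection_frequency <- function(matrix, labels) {
  case <- as_case_flag(labels)
  if (length(case) != nrow(matrix)) stop("labels must cover all matrix rows")
  if (!any(case) || all(case)) stop("both groups must be non-empty")
  data.frame(peptide_id = colnames(matrix),
             freq_case = colMeans(matrix[case, , drop = FALSE] > 0),
             freq_control = colMeans(matrix[!case, , drop = FALSE] > 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum screen over all peptides
#'
#' Two-sided rank-sum test per peptide of case vs control amplitudes, with
#' undetected values entering as amplitude 0 (tied at the bottom of the
#' ranking). The exact null distribution is used for combined n <= 25
#' without ties; otherwise the normal approximation with mid-rank tie
#' correction. A constant column is degenerate: p = 1 with a flag.
#'
#' @inheritParams detection_frequency
#' @return data.frame (peptide_id, p_raw, degenerate)
#' @export
wilcoxon_screen <- function(matrix, labels) {
  case <- as_case_flag(labels)
  if (sum(case) < 2 || sum(!case) < 2) stop("both groups need >= 2 samples")
  n <- nrow(matrix)
  res <- vapply(seq_len(ncol(matrix)), function(j) {
    x <- matrix[case, j]; y <- matrix[!case, j]
    if (length(unique(c(x, y))) == 1L) return(c(1, 1))
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- (n <= 25) && !ties
    p <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                             correct = !exact)$p.value)
    c(min(p, 1), 0)
  }, numeric(2))
  data.frame(peptide_id = colnames(matrix), p_raw = res[1, ],
             degenerate = res[2, ] == 1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone, capped at 1, input
#' order preserved.
#' @param p_raw raw p-values in `[0, 1]`
#' @return adjusted p-values
#' @export
bh_adjust <- function(p_raw) {
  check_prob(p_raw, "p_raw")
  stats::p.adjust(p_raw, method = "BH")
}

#' Select the biomarker panel
#'
#' Keeps peptides detected at `freq_min` or higher in at least one group
#' whose adjusted p-value is below `alpha`; the panel is ordered by
#' adjusted p (ties by peptide id). `use_adjusted = FALSE` applies the
#' significance cut to raw p-values instead.
#'
#' @param records data.frame with peptide_id, freq_case, freq_control,
#'   p_raw, p_adj (as assembled by [discover_panel()])
#' @param freq_min minimum group detection frequency (inclusive)
#' @param alpha significance level (exclusive)
#' @param use_adjusted apply `alpha` to adjusted p-values
#' @return a `biomarker_panel`: the filtered, ordered records plus the
#'   selection parameters
#' @export
select_panel <- function(records, freq_min = 0.70, alpha = 0.05,
                         use_adjusted = TRUE) {
  p <- if (use_adjusted) records$p_adj else records$p_raw
  keep <- pmax(records$freq_case, records$freq_control) >= freq_min & p < alpha
  sel <- records[keep, , drop = FALSE]
  sel <- sel[order(if (use_adjusted) sel$p_adj else sel$p_raw, sel$peptide_id), ,
             drop = FALSE]
  rownames(sel) <- NULL
  structure(list(records = sel, freq_min = freq_min, alpha = alpha,
                 use_adjusted = use_adjusted, n_selected = nrow(sel),
                 n_tested = nrow(records)),
            class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("Biomarker panel: %d of %d peptides (freq >= %.0f%%, %s p < %g)\n",
              x$n_selected, x$n_tested, 100 * x$freq_min,
              if (x$use_adjusted) "adjusted" else "raw", x$alpha))
  invisible(x)
}

#' Signed differential excretion of a peptide
#'
#' Group means are taken over *all* samples, counting 0 for undetected, and
#' multiplied by the group's detection frequency. If the case product
#' exceeds the control product the ratio case/control is returned; if it is
#' smaller, the negated reciprocal control/case; equal products give +1.
#' A zero product makes the ratio undefined: NA with an attribute flag.
#'
#' @inheritParams detection_frequency
#' @param peptide_id column to evaluate
#' @return signed ratio (|DE| >= 1), or NA with attribute `undefined`
#' @export
differential_excretion <- function(matrix, labels, peptide_id) {
  if (!peptide_id %in% colnames(matrix)) {
    stop(sprintf("peptide '%s' absent from matrix", peptide_id))
  }
  case <- as_case_flag(labels)
  x <- matrix[, peptide_id]
  prod_case <- mean(x[case]) * mean(x[case] > 0)
  prod_ctrl <- mean(x[!case]) * mean(x[!case] > 0)
  if (prod_case == 0 || prod_ctrl == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  if (prod_case > prod_ctrl) prod_case / prod_ctrl
  else if (prod_case < prod_ctrl) -prod_ctrl / prod_case
  else 1.0
}

#' Run the full discovery stage
#'
#' Computes frequencies, raw Wilcoxon p-values, BH-adjusted p-values, and
#' differential excretion for every peptide, then applies the panel filter.
#' @inheritParams detection_frequency
#' @inheritParams select_panel
#' @return a `biomarker_panel` whose records carry all per-peptide columns
#' @export
discover_panel <- function(matrix, labels, freq_min = 0.70, alpha = 0.05,
                           use_adjusted = TRUE) {
  freq <- detection_frequency(matrix, labels)
  wl <- wilcoxon_screen(matrix, labels)
  records <- merge(freq, wl, by = "peptide_id", sort = FALSE)
  records$p_adj <- bh_adjust(records$p_raw)
  records$differential_excretion <- vapply(records$peptide_id, function(id) {
    as.numeric(differential_excretion(matrix, labels, id))
  }, numeric(1))
  select_panel(records, freq_min = freq_min, alpha = alpha,
               use_adjusted = use_adjusted)
}
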