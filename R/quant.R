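# The study's printed quantification formulas.

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target - Ct_ref)[TF-transfected] -
#' (Ct_target - Ct_ref)[empty vector]`; the returned fold change is
#' `2^-ddCt`, with values above 1 meaning higher target expression in the
#' TF-transfected condition. Technical replicates should be averaged on the
#' Ct scale before calling this (pass vectors and they are).
#'
#' @param ct_target_tf,ct_ref_tf Cycle thresholds for target and reference
#'   gene in the TF-transfected condition (vectors of technical replicates
#'   are averaged).
#' @param ct_target_ev,ct_ref_ev Same for the empty-vector condition.
#' @return Fold change (positive scalar).
#' @export
fold_change_ddct <- function(ct_target_tf, ct_ref_tf,
                             ct_target_ev, ct_ref_ev) {
  cts <- c(ct_target_tf, ct_ref_tf, ct_target_ev, ct_ref_ev)
  if (any(!is.finite(cts))) stop("non-finite Ct value")
  if (any(cts < 10 | cts > 40)) {
    warning("Ct value(s) outside the typical 10-40 range")
  }
  ddct <- (mean(ct_target_tf) - mean(ct_ref_tf)) -
    (mean(ct_target_ev) - mean(ct_ref_ev))
  2^(-ddct)
}

#' Ratiometric dual-luciferase normalization
#'
#' Reporter counts divided by the constitutive control counts, further
#' divided by the batch-calibrator ratio when one is supplied (per
#' experiment by default; calibrate per plate by passing per-plate ratios).
#'
#' @param reporter_lum Experimental reporter luminescence counts.
#' @param control_lum Constitutive control luminescence counts (> 0).
#' @param batch_calibrator_ratio Optional calibrator reporter/control ratio.
#' @return Normalized ratio (vectorized).
#' @export
normalize_luminescence <- function(reporter_lum, control_lum,
                                   batch_calibrator_ratio = NULL) {
  if (any(control_lum <= 0)) stop("control luminescence must be > 0")
  r <- reporter_lum / control_lum
  if (!is.null(batch_calibrator_ratio)) r <- r / batch_calibrator_ratio
  r
}

#' GO category odds ratio and enrichment call
#'
#' `OR = (k_in / n_in) / (k_all / n_all)`: the category's frequency in the
#' input set over its frequency in the cluster universe. A term is enriched
#' iff `p_value < 0.05` and `OR > 1`. The enrichment p-value is accepted as
#' input (the length-bias-corrected p comes from an external tool); a plain
#' hypergeometric p-value is available via [go_hypergeom_p()] as a clearly
#' non-equivalent fallback.
#'
#' @param k_in Genes of the category in the input set.
#' @param n_in All genes in the input set (> 0).
#' @param k_all Genes of the category in the cluster universe (> 0).
#' @param n_all Genes in all clusters (> 0).
#' @param p_value Enrichment p-value (default `NA`: enrichment flag is `NA`).
#' @return List with `odds_ratio` and logical `enriched`.
#' @export
go_odds_ratio <- function(k_in, n_in, k_all, n_all, p_value = NA_real_) {
  if (n_in <= 0 || n_all <= 0 || k_all <= 0) stop("zero denominator")
  if (k_in < 0 || k_in > n_in || k_all > n_all || k_in > k_all) {
    stop("inconsistent counts")
  }
  or <- (k_in / n_in) / (k_all / n_all)
  list(odds_ratio = or,
       enriched = if (is.na(p_value)) NA else (p_value < 0.05 && or > 1))
}

#' Hypergeometric enrichment p-value (fallback)
#'
#' Upper-tail hypergeometric probability of drawing at least `k_in` category
#' genes in `n_in` draws from a universe of `n_all` genes containing `k_all`
#' category genes. This is a plain over-representation test, not equivalent
#' to length-bias-corrected enrichment.
#'
#' @inheritParams go_odds_ratio
#' @return A p-value.
#' @export
go_hypergeom_p <- function(k_in, n_in, k_all, n_all) {
  phyper(k_in - 1, k_all, n_all - k_all, n_in, lower.tail = FALSE)
}
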