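## Progression-free-survival ratio evaluation of truncal-mutation-directed
## therapy: each patient serves as their own control, comparing PFS on the
## genotype-directed therapy with PFS on the immediately preceding therapy.

## round half away from zero to `digits` significant figures; a tiny
## relative nudge counters binary representation (6.1/4 must print 1.53,
## not 1.52)
signif_away <- function(x, digits = 3) {
  out <- x
  nz <- !is.na(x) & x != 0
  e <- floor(log10(abs(x[nz]))) - digits + 1
  m <- x[nz] / 10^e * (1 + 1e-12)
  r <- as.integer(sign(m) * floor(abs(m) + 0.5))
  ## reassemble through a decimal string so the result is the closest
  ## double to the printed value (102 * 10^-1 in binary is not 10.2)
  out[nz] <- as.numeric(paste0(r, "e", e))
  out
}

#' PFS ratio and clinical-benefit call
#'
#' Ratio of the progression-free survival on truncal-mutation-directed
#' therapy to the PFS on the most recent prior therapy. A ratio at or above
#' the threshold (default 1.3) defines clinical benefit. The reported ratio
#' is rounded half-away-from-zero to 3 significant figures; the benefit
#' call uses the unrounded value.
#'
#' @param pfs_tdt PFS in months on the truncal-directed therapy (> 0,
#'   vectorized).
#' @param pfs_prior PFS in months on the immediately preceding therapy
#'   (> 0).
#' @param threshold Benefit threshold on the ratio (inclusive).
#' @return data.frame with `pfs_tdt`, `pfs_prior`, `ratio` (3 significant
#'   figures), `ratio_raw` (full precision) and logical `benefit`.
#' @examples
#' pfs_ratio(25.5, 2.5) # ratio 10.2, benefit TRUE
#' pfs_ratio(1.9, 2.0)  # ratio 0.95, benefit FALSE
#' @export
pfs_ratio <- function(pfs_tdt, pfs_prior, threshold = 1.3) {
  if (any(pfs_tdt <= 0) || any(pfs_prior <= 0)) {
    stop("PFS values must be positive")
  }
  raw <- pfs_tdt / pfs_prior
  data.frame(pfs_tdt = pfs_tdt, pfs_prior = pfs_prior,
             ratio = signif_away(raw, 3), ratio_raw = raw,
             benefit = raw >= threshold)
}

#' Cohort summary of PFS outcomes
#'
#' Median PFS on directed therapy and median PFS ratio over the selected
#' outcomes (typically the patients whose actionable truncal mutation was
#' targeted). Medians of the unrounded ratios, reported at 2 significant
#' figures; an even count takes the midpoint.
#'
#' @param outcomes data.frame from [pfs_ratio()] (optionally pre-filtered
#'   to the actionable-truncal-targeted patients).
#' @return List with `median_pfs_tdt`, `median_ratio`, `n`; both medians
#'   `NA` (reported missing, not zero) when `outcomes` is empty.
#' @export
cohort_summary <- function(outcomes) {
  if (!nrow(outcomes)) {
    warning("no outcomes after filtering; medians undefined")
    return(list(median_pfs_tdt = NA_real_, median_ratio = NA_real_, n = 0L))
  }
  list(median_pfs_tdt = signif_away(stats::median(outcomes$pfs_tdt), 2),
       median_ratio = signif_away(stats::median(outcomes$ratio_raw), 2),
       n = nrow(outcomes))
}

#' Evaluate a clinical outcome table
#'
#' Convenience wrapper: applies [pfs_ratio()] to a table loaded with
#' [load_clinical()] and, when truncal status of the targeted alteration is
#' known, joins it in.
#'
#' @param clinical data.frame with `patient_id`, `pfs_prior_months`,
#'   `pfs_tdt_months`, optional `truncal_status` (truncal/branch/unknown).
#' @param threshold Benefit threshold.
#' @return data.frame, one row per patient.
#' @export
evaluate_outcomes <- function(clinical, threshold = 1.3) {
  out <- cbind(patient_id = clinical$patient_id,
               pfs_ratio(clinical$pfs_tdt_months, clinical$pfs_prior_months,
                         threshold = threshold))
  out$truncal_status <- if ("truncal_status" %in% names(clinical)) {
    clinical$truncal_status
  } else {
    "unknown"
  }
  out
}
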