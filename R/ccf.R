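## Single-biopsy in-silico prediction of truncal status. Ground truth is
## the multi-biopsy classification; the predictor sees one biopsy at a time
## and thresholds either the allele frequency or the cancer cell fraction.

#' Allele frequency from read counts
#'
#' AF = alternate reads / (alternate + reference reads).
#'
#' @param alt_count,ref_count Non-negative read counts (vectorized).
#' @return Numeric fraction(s) in `[0, 1]`.
#' @examples
#' compute_af(7, 93) # 0.07
#' @export
compute_af <- function(alt_count, ref_count) {
  if (any(alt_count < 0 | ref_count < 0)) stop("negative read count")
  depth <- alt_count + ref_count
  if (any(depth == 0)) stop("zero sequencing depth")
  alt_count / depth
}

#' Closed-form cancer cell fraction estimate
#'
#' The fraction of cancer cells carrying a variant, given the observed
#' allele frequency and the local genomic context:
#' `CCF = AF * (purity * tumor_cn + normal_cn * (1 - purity)) /
#' (purity * multiplicity)`, clipped to `[0, 1]`. This is the standard
#' single-site estimator used when purity and copy number are already
#' known; full purity/ploidy inference is out of scope.
#'
#' @param af Allele frequency in `[0, 1]`.
#' @param purity Tumor cell fraction of the sample, in `(0, 1]`.
#' @param tumor_cn Local total copy number in tumor cells (default 2).
#' @param multiplicity Number of mutated copies per carrying cell
#'   (default 1).
#' @param normal_cn Copy number in contaminating normal cells (default 2).
#' @return CCF value(s) in `[0, 1]`; attribute `n_clipped` counts values
#'   truncated at the boundaries.
#' @examples
#' estimate_ccf(0.25, purity = 0.5) # 1
#' estimate_ccf(0.2, purity = 0.8, tumor_cn = 3) # 0.7
#' @export
estimate_ccf <- function(af, purity, tumor_cn = 2, multiplicity = 1,
                         normal_cn = 2) {
  if (any(purity <= 0 | purity > 1)) stop("purity must be in (0, 1]")
  if (any(multiplicity < 1)) stop("multiplicity must be >= 1")
  if (any(af < 0 | af > 1)) stop("af must be in [0, 1]")
  raw <- af * (purity * tumor_cn + normal_cn * (1 - purity)) /
    (purity * multiplicity)
  ccf <- pmin(pmax(raw, 0), 1)
  structure(ccf, n_clipped = sum(raw > 1 | raw < 0))
}

#' Threshold classification of clonality
#'
#' A variant is called truncal when its metric value is greater than or
#' equal to the threshold (inclusive boundary, recorded in the output
#' metadata), branch otherwise.
#'
#' @param values Named numeric vector of per-variant metric values (AF or
#'   CCF).
#' @param threshold Scalar threshold.
#' @return Character vector (`"truncal"`/`"branch"`) named like `values`,
#'   with attribute `rule = ">="`.
#' @export
classify_by_threshold <- function(values, threshold) {
  stopifnot(is.numeric(values), length(threshold) == 1)
  structure(ifelse(values >= threshold, "truncal", "branch"),
            names = names(values), rule = ">=")
}

## Per-biopsy accuracy of threshold classification for one patient, over a
## threshold grid. For biopsy i the variants assessed are those present in
## i; a prediction is correct when (metric >= thr) agrees with the
## multi-biopsy truncal truth. Returns a thresholds x biopsies accuracy
## matrix averaged later per the averaging formula (mean over biopsies,
## then over patients).
patient_accuracy <- function(matrix, metric) {
  vals <- if (metric == "af") matrix$af else matrix$ccf
  if (is.null(vals)) return(NULL)
  truth <- classify_clonality(matrix) == "truncal"
  list(values = vals, truth = truth)
}

#' Grid search for the best clonality threshold
#'
#' For every threshold in the grid, classifies each variant of each biopsy
#' by its single-biopsy metric value, scores it against the multi-biopsy
#' truncal truth, averages the accuracy over the patient's biopsies
#' (each biopsy's denominator is the number of variants present in it),
#' then averages across the patients of each group. The best threshold is
#' the smallest grid value attaining the maximum average accuracy.
#'
#' @param matrices Named list of [presence_matrix()] objects (one per
#'   patient), carrying AF and/or CCF overlays.
#' @param metric `"af"` or `"ccf"`.
#' @param grid Numeric vector of thresholds (e.g. from
#'   [pipeline_config()]).
#' @param grouping `"cohort"` (one group), `"patient"` (each patient its
#'   own group) or `"cancer_type"` (requires `groups`).
#' @param groups Named character vector mapping patient id to group label
#'   (used when `grouping = "cancer_type"`).
#' @return A `sweep_result` object: list with `metric`, `grouping`, `grid`,
#'   `rule` (">=", smallest-argmax tie break), `by_group` (data.frame:
#'   group, best_threshold, best_accuracy, n_patients), `accuracy`
#'   (group x threshold matrix), `skipped` (patients without the metric or
#'   without variants, reported not fatal).
#' @export
sweep_threshold <- function(matrices, metric = c("af", "ccf"), grid,
                            grouping = c("cohort", "cancer_type", "patient"),
                            groups = NULL) {
  metric <- match.arg(metric)
  grouping <- match.arg(grouping)
  stopifnot(length(grid) >= 1)
  if (grouping == "cancer_type" && is.null(groups)) {
    stop("grouping by cancer type needs a patient -> type mapping")
  }

  per_patient <- list()
  skipped <- character()
  for (pm in matrices) {
    dat <- patient_accuracy(pm, metric)
    if (is.null(dat) || nrow(pm$presence) == 0 || ncol(pm$presence) < 2) {
      skipped <- c(skipped, pm$patient_id)
      next
    }
    acc <- vapply(grid, function(thr) {
      per_bx <- vapply(seq_len(ncol(dat$values)), function(i) {
        present <- !is.na(dat$values[, i])
        if (!any(present)) return(NA_real_)
        pred <- dat$values[present, i] >= thr
        mean(pred == dat$truth[present])
      }, numeric(1))
      mean(per_bx, na.rm = TRUE)
    }, numeric(1))
    per_patient[[pm$patient_id]] <- acc
  }
  if (!length(per_patient)) {
    stop("no patient with usable ", toupper(metric), " values")
  }

  grp_of <- switch(grouping,
    cohort = stats::setNames(rep("cohort", length(per_patient)),
                             names(per_patient)),
    patient = stats::setNames(names(per_patient), names(per_patient)),
    cancer_type = {
      g <- groups[names(per_patient)]
      if (anyNA(g)) stop("missing cancer type for: ",
                         paste(names(per_patient)[is.na(g)], collapse = ", "))
      g
    })

  acc_mat <- t(vapply(split(names(per_patient), grp_of), function(ids) {
    colMeans(do.call(rbind, per_patient[ids]))
  }, numeric(length(grid))))
  rownames(acc_mat) <- names(split(names(per_patient), grp_of))
  colnames(acc_mat) <- format(grid)

  ## smallest grid value attaining the max, with a float-noise guard
  argmin_best <- function(r) grid[which(r >= max(r) - 1e-12)[1]]
  by_group <- data.frame(
    group = rownames(acc_mat),
    best_threshold = apply(acc_mat, 1, argmin_best),
    best_accuracy = apply(acc_mat, 1, max),
    n_patients = as.integer(table(grp_of)[rownames(acc_mat)]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(metric = toupper(metric), grouping = grouping, grid = grid,
                 rule = ">= threshold, smallest argmax on ties",
                 by_group = by_group, accuracy = acc_mat,
                 per_patient = per_patient, skipped = skipped),
            class = "sweep_result")
}

#' Compare AF- and CCF-based threshold sweeps
#'
#' Pairs the two sweeps by patient, takes each patient's best achievable
#' accuracy under either metric, and reports the mean paired improvement of
#' the first sweep over the second with a Wilcoxon signed-rank p-value.
#'
#' @param sweep_a,sweep_b `sweep_result` objects computed on the same
#'   patients (typically AF vs CCF).
#' @return List with `per_patient` (data.frame patient / accuracy under
#'   each metric / difference), `mean_improvement`, `p_value` (`NA` with
#'   fewer than 2 informative pairs).
#' @export
compare_metrics <- function(sweep_a, sweep_b) {
  pa <- names(sweep_a$per_patient)
  pb <- names(sweep_b$per_patient)
  common <- intersect(pa, pb)
  if (!setequal(pa, pb)) {
    stop("sweeps cover different patients; unpaired: ",
         paste(union(setdiff(pa, pb), setdiff(pb, pa)), collapse = ", "))
  }
  best_a <- vapply(sweep_a$per_patient[common], max, numeric(1))
  best_b <- vapply(sweep_b$per_patient[common], max, numeric(1))
  d <- best_a - best_b
  p <- if (length(common) >= 2) paired_signed_rank_p(best_a, best_b) else NA_real_
  list(per_patient = data.frame(patient_id = common,
                                best_a = unname(best_a),
                                best_b = unname(best_b),
                                difference = unname(d),
                                stringsAsFactors = FALSE),
       metric_a = sweep_a$metric, metric_b = sweep_b$metric,
       mean_improvement = mean(d), p_value = p)
}
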