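## Combinatorial saturation analysis. For a patient with b QC-passed
## biopsies and each subset size k in 1..b, every one of the C(b, k)
## biopsy subsets is enumerated (deterministic lexicographic order via
## utils::combn) and three per-subset statistics are taken:
##   unique  -- variants present in at least one biopsy of the subset
##   ptv     -- putative truncal variants: present in all biopsies of the
##              subset (the subset stands in for the whole lesion)
##   ppv     -- C / ptv, where C is the truncal count over all b biopsies;
##              measures how many subset-defined PTVs are truly truncal.
## "Permutation combinations" in this analysis means combinations: unions
## and intersections are order-invariant, so n = C(b, k).

subset_values <- function(matrix, k) {
  b <- ncol(matrix$presence)
  if (k < 1 || k > b) stop("k out of range 1..", b)
  subsets <- utils::combn(b, k)
  pres <- matrix$presence
  C <- sum(rowSums(pres) == b)
  out <- data.frame(
    subset_id = apply(subsets, 2, function(s) {
      paste(colnames(pres)[s], collapse = "+")
    }),
    unique = apply(subsets, 2, function(s) {
      sum(rowSums(pres[, s, drop = FALSE]) > 0)
    }),
    ptv = apply(subsets, 2, function(s) {
      sum(rowSums(pres[, s, drop = FALSE]) == k)
    }),
    stringsAsFactors = FALSE
  )
  out$ppv <- ifelse(out$ptv > 0, C / out$ptv, NA_real_)
  attr(out, "truncal_count") <- C
  out
}

#' Average number of unique variants over biopsy subsets of size k
#'
#' Mean over all `C(b, k)` subsets of the number of variants present in at
#' least one biopsy of the subset.
#'
#' @param matrix A [presence_matrix()].
#' @param k Subset size, `1 <= k <= b`.
#' @return Numeric mean; attribute `per_subset` carries the per-subset
#'   values (for boxplots), in lexicographic subset order.
#' @export
avg_unique <- function(matrix, k) {
  v <- subset_values(matrix, k)
  structure(mean(v$unique), per_subset = stats::setNames(v$unique, v$subset_id))
}

#' Average number of putative truncal variants over subsets of size k
#'
#' Mean over all `C(b, k)` subsets of the number of variants present in
#' *every* biopsy of the subset.
#'
#' @inheritParams avg_unique
#' @return Numeric mean with `per_subset` attribute.
#' @export
avg_ptv <- function(matrix, k) {
  v <- subset_values(matrix, k)
  structure(mean(v$ptv), per_subset = stats::setNames(v$ptv, v$subset_id))
}

#' Average positive predictive value over subsets of size k
#'
#' For each subset, PPV = C / PTV where C is the truncal count defined over
#' all b biopsies and PTV the subset's putative truncal count. Subsets with
#' PTV = 0 give an undefined 0/0 (this happens for every subset when the
#' patient has no truncal variants) and are excluded from the mean; the
#' number excluded is reported.
#'
#' @inheritParams avg_unique
#' @return Numeric mean (`NA` when every subset was excluded), with
#'   attributes `per_subset` and `n_excluded`.
#' @export
avg_ppv <- function(matrix, k) {
  v <- subset_values(matrix, k)
  ok <- !is.na(v$ppv)
  structure(if (any(ok)) mean(v$ppv[ok]) else NA_real_,
            per_subset = stats::setNames(v$ppv, v$subset_id),
            n_excluded = sum(!ok))
}

#' Full saturation profile for one patient
#'
#' Computes `avg_unique`, `avg_ptv` and `avg_ppv` for every subset size
#' k = 1..b, together with the per-subset values in long format.
#'
#' @param matrix A [presence_matrix()].
#' @param panel_name Optional panel label carried into the output.
#' @return A `saturation_profile` object: list with `patient_id`, `panel`,
#'   `b`, `summary` (data.frame k/avg_unique/avg_ptv/avg_ppv/ppv_excluded)
#'   and `per_subset` (long data.frame).
#' @export
saturation_profile <- function(matrix, panel_name = NA_character_) {
  stopifnot(inherits(matrix, "presence_matrix"))
  b <- ncol(matrix$presence)
  rows <- vector("list", b)
  long <- vector("list", b)
  for (k in seq_len(b)) {
    v <- subset_values(matrix, k)
    ok <- !is.na(v$ppv)
    rows[[k]] <- data.frame(
      k = k,
      avg_unique = mean(v$unique),
      avg_ptv = mean(v$ptv),
      avg_ppv = if (any(ok)) mean(v$ppv[ok]) else NA_real_,
      ppv_excluded = sum(!ok)
    )
    long[[k]] <- cbind(k = k, v)
  }
  structure(list(patient_id = matrix$patient_id, panel = panel_name, b = b,
                 summary = do.call(rbind, rows),
                 per_subset = do.call(rbind, long)),
            class = "saturation_profile")
}

#' Per-step increments of the saturation statistics across a cohort
#'
#' For each patient, the change in `avg_unique` and `avg_ptv` from k to k+1
#' biopsies; across patients, the mean and sample sd per step and pooled
#' over all steps. The k = 1 to 2 drop in putative truncal variants -- the
#' steepest step -- is reported separately.
#'
#' @param profiles List of [saturation_profile()] objects.
#' @return List with `per_patient` (long data.frame of deltas), `per_step`
#'   (mean/sd by statistic and step), `pooled` (mean/sd by statistic over
#'   all steps and patients) and `ptv_drop_1_to_2` (mean/sd of the first
#'   PTV drop, as a positive magnitude).
#' @export
increment_stats <- function(profiles) {
  per <- lapply(profiles, function(p) {
    s <- p$summary
    if (nrow(s) < 2) return(NULL)
    data.frame(patient_id = p$patient_id,
               step = paste0(s$k[-nrow(s)], "->", s$k[-1]),
               k_from = s$k[-nrow(s)],
               d_unique = diff(s$avg_unique),
               d_ptv = diff(s$avg_ptv),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  if (is.null(per)) stop("no patient with >= 2 biopsies")
  agg <- function(x, by) {
    mu <- tapply(x, by, mean)
    sdv <- tapply(x, by, stats::sd)
    data.frame(step = names(mu), mean = as.numeric(mu), sd = as.numeric(sdv),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  per_step <- rbind(
    cbind(statistic = "unique", agg(per$d_unique, per$step)),
    cbind(statistic = "ptv", agg(per$d_ptv, per$step))
  )
  pooled <- data.frame(
    statistic = c("unique", "ptv"),
    mean = c(mean(per$d_unique), mean(per$d_ptv)),
    sd = c(stats::sd(per$d_unique), stats::sd(per$d_ptv)),
    stringsAsFactors = FALSE
  )
  first <- per[per$k_from == 1, , drop = FALSE]
  ptv_drop <- c(mean = mean(-first$d_ptv), sd = stats::sd(-first$d_ptv))
  list(per_patient = per, per_step = per_step, pooled = pooled,
       ptv_drop_1_to_2 = ptv_drop)
}

## Paired Wilcoxon signed-rank p-value with the standard conventions: zero
## differences dropped; exact distribution when < 25 informative pairs and
## no ties, normal approximation otherwise; p = 1 when every pair is zero.
paired_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) return(1)
  exact <- length(d) < 25 && !any(duplicated(abs(d)))
  suppressWarnings(stats::wilcox.test(d, exact = exact)$p.value)
}

#' Minimum number of biopsies for a saturating statistic
#'
#' For each step k to k+1, a paired Wilcoxon signed-rank test across
#' patients compares the per-patient statistic (`avg_unique` or `avg_ptv`)
#' at k biopsies with the value at k+1. The smallest k whose step is not
#' significant (p >= alpha) is returned; when every step is significant the
#' full biopsy count b is returned with flag `">=b"` -- adding samples still
#' changes the statistic, so saturation has not been reached.
#'
#' Patients contribute to the steps their biopsy count supports; steps with
#' fewer than 2 contributing patients cannot be tested and stop the search.
#'
#' @param profiles List of [saturation_profile()] objects (>= 2 patients;
#'   >= 5 recommended, below which the exact test is badly powered).
#' @param alpha Significance level.
#' @param statistic `"unique"` or `"ptv"`.
#' @return List with `k_min`, `flag` (`""` or `">=b"`), and `steps`
#'   (data.frame of step, n pairs, p-value, significant).
#' @export
min_samples_required <- function(profiles, alpha = 0.05,
                                 statistic = c("unique", "ptv")) {
  statistic <- match.arg(statistic)
  if (length(profiles) < 2) stop("need >= 2 patients")
  if (length(profiles) < 5) {
    warning("fewer than 5 patients: signed-rank test has little power")
  }
  col <- paste0("avg_", statistic)
  b_max <- max(vapply(profiles, function(p) p$b, 1L))
  steps <- list()
  k_min <- NA_integer_
  for (k in seq_len(b_max - 1)) {
    at_k <- vapply(profiles, function(p) {
      if (p$b >= k + 1) p$summary[[col]][k] else NA_real_
    }, numeric(1))
    at_k1 <- vapply(profiles, function(p) {
      if (p$b >= k + 1) p$summary[[col]][k + 1] else NA_real_
    }, numeric(1))
    ok <- !is.na(at_k)
    if (sum(ok) < 2) break
    p_val <- paired_signed_rank_p(at_k1[ok], at_k[ok])
    sig <- p_val < alpha
    steps[[k]] <- data.frame(step = paste0(k, "->", k + 1), n = sum(ok),
                             p_value = p_val, significant = sig,
                             stringsAsFactors = FALSE)
    if (!sig && is.na(k_min)) k_min <- k
  }
  flag <- ""
  if (is.na(k_min)) {
    k_min <- b_max
    flag <- ">=b"
  }
  list(k_min = as.integer(k_min), flag = flag,
       steps = do.call(rbind, steps), statistic = statistic, alpha = alpha)
}

#' Friedman test on per-biopsy mutational loads
#'
#' Tests whether mutational load differs systematically between biopsy
#' positions across patients (rows = patients as blocks, columns = biopsy
#' slots). Requires a complete load table: every patient contributes the
#' same number of biopsies.
#'
#' @param loads Numeric matrix, patients x biopsy slots (>= 3 patients).
#' @return List with `statistic` (Friedman chi-squared), `df`, `p_value`.
#' @export
friedman_load_test <- function(loads) {
  loads <- as.matrix(loads)
  if (nrow(loads) < 3) stop("need >= 3 patients for the Friedman test")
  if (anyNA(loads)) stop("load table must be complete (no NA)")
  ## constant rows carry no rank information; with all rows constant the
  ## statistic is 0 and p = 1, which friedman.test reports as NaN
  ft <- suppressWarnings(stats::friedman.test(loads))
  p <- ft$p.value
  if (is.nan(ft$statistic) || is.nan(p)) {
    ft$statistic <- 0
    p <- 1
  }
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p_value = p)
}
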