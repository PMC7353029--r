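## Clonality classification over the analyzed (QC-passed) biopsies of one
## lesion. The denominator is always the number of biopsy columns actually
## analyzed for that patient (2-4 in practice), so a 2-biopsy patient can
## still contribute truncal calls; with 2 columns the branch class is empty
## by construction.

#' Classify variants as truncal, branch or private
#'
#' A variant is *truncal* when present in every analyzed biopsy, *private*
#' when present in exactly one, and *branch* otherwise (more than one but
#' not all). Binary copy-number events encoded as rows of a presence matrix
#' pass through the identical classifier.
#'
#' @param matrix A [presence_matrix()] with at least two biopsy columns.
#' @return A factor (levels `truncal`, `branch`, `private`) named by variant
#'   key, with attribute `counts` (named integer vector over the three
#'   labels).
#' @examples
#' pm <- presence_matrix("P1", matrix(c(TRUE, TRUE, TRUE, FALSE),
#'   2, 2, dimnames = list(c("v1", "v2"), c("B1", "B2"))))
#' classify_clonality(pm)
#' @export
classify_clonality <- function(matrix) {
  stopifnot(inherits(matrix, "presence_matrix"))
  b <- ncol(matrix$presence)
  if (b < 2) stop("clonality requires >= 2 analyzed biopsies")
  m <- rowSums(matrix$presence)
  lab <- ifelse(m == b, "truncal", ifelse(m == 1L, "private", "branch"))
  lab <- factor(lab, levels = c("truncal", "branch", "private"))
  names(lab) <- rownames(matrix$presence)
  attr(lab, "counts") <- stats::setNames(as.integer(table(lab)), levels(lab))
  lab
}

#' Per-patient clonality proportions
#'
#' Fractions of variants labelled truncal, branch and private; they sum to 1.
#'
#' @param labels Factor returned by [classify_clonality()].
#' @return Named numeric vector `c(truncal=, branch=, private=)`, or all-`NA`
#'   (with a warning) when no variants were labelled -- an empty patient is
#'   reported as missing, never as zero.
#' @export
clonality_proportions <- function(labels) {
  n <- length(labels)
  if (n == 0) {
    warning("no labelled variants; proportions undefined")
    return(c(truncal = NA_real_, branch = NA_real_, private = NA_real_))
  }
  tab <- table(factor(labels, levels = c("truncal", "branch", "private")))
  stats::setNames(as.numeric(tab) / n, names(tab))
}

#' Cohort-level clonality summary
#'
#' Mean and sample standard deviation of the per-patient proportions.
#'
#' @param label_list List of factors from [classify_clonality()], one per
#'   patient.
#' @return data.frame with rows truncal/branch/private and columns
#'   `mean`, `sd`, `n_patients`.
#' @export
cohort_clonality <- function(label_list) {
  props <- t(vapply(label_list, clonality_proportions, numeric(3)))
  data.frame(
    label = colnames(props),
    mean = colMeans(props, na.rm = TRUE),
    sd = apply(props, 2, stats::sd, na.rm = TRUE),
    n_patients = colSums(!is.na(props)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Non-synonymous somatic mutational load and diversity
#'
#' The load of a biopsy is the number of non-synonymous somatic variants
#' present in it (a column sum of the presence matrix). Diversity summarizes
#' how much the load differs between regions of the same lesion: the mean
#' and sample standard deviation of the absolute load difference over all
#' unordered biopsy pairs.
#'
#' @param matrix A [presence_matrix()] restricted to non-synonymous somatic
#'   variants.
#' @return List with `per_biopsy` (named integer), `mean`, `sd` (sample sd,
#'   n-1 denominator), `diversity_mean`, `diversity_sd`.
#' @export
mutational_load <- function(matrix) {
  stopifnot(inherits(matrix, "presence_matrix"))
  loads <- colSums(matrix$presence)
  pairs <- utils::combn(length(loads), 2)
  diffs <- abs(loads[pairs[1, ]] - loads[pairs[2, ]])
  list(per_biopsy = stats::setNames(as.integer(loads), names(loads)),
       mean = mean(loads),
       sd = stats::sd(loads),
       diversity_mean = mean(diffs),
       diversity_sd = stats::sd(diffs))
}

#' Restrict a presence matrix to a gene panel
#'
#' Retains only the variant rows whose annotated gene belongs to the panel
#' (symbols compared uppercase). A row filter cannot create all-absent rows.
#' An empty intersection is legal -- small panels frequently match nothing in
#' a given patient -- and is flagged via the `"empty"` attribute rather than
#' raised as an error.
#'
#' @param matrix A [presence_matrix()] with gene annotations.
#' @param panel A [panel_definition()].
#' @return A `presence_matrix` (possibly with zero rows; check
#'   `attr(, "empty")`).
#' @export
filter_panel <- function(matrix, panel) {
  stopifnot(inherits(matrix, "presence_matrix"),
            inherits(panel, "panel_definition"))
  if (is.null(matrix$genes)) stop("matrix has no gene annotations")
  keep <- matrix$genes %in% panel$genes
  sub <- function(m) if (is.null(m)) NULL else m[keep, , drop = FALSE]
  out <- presence_matrix(matrix$patient_id,
                         matrix$presence[keep, , drop = FALSE],
                         af = sub(matrix$af), ccf = sub(matrix$ccf),
                         genes = matrix$genes[keep])
  attr(out, "panel") <- panel$name
  attr(out, "empty") <- !any(keep)
  out
}

#' Clonality of driver-gene variants
#'
#' Restricts the labelled variants to a user-supplied driver gene list and
#' reports, per driver variant, its gene, clonality label and (when the
#' matrix carries them) mean allele frequency and cancer cell fraction
#' across the biopsies where it is present, plus the overall fraction of
#' driver variants that are truncal.
#'
#' @param matrix A [presence_matrix()] with gene annotations.
#' @param labels Factor from [classify_clonality()] on the same matrix.
#' @param driver_genes Character vector of driver gene symbols.
#' @return List with `report` (data.frame) and `fraction_truncal` (`NA` when
#'   no driver variants are present).
#' @export
annotate_drivers <- function(matrix, labels, driver_genes) {
  stopifnot(inherits(matrix, "presence_matrix"))
  if (is.null(matrix$genes)) stop("matrix has no gene annotations")
  driver_genes <- toupper(driver_genes)
  keep <- which(matrix$genes %in% driver_genes)
  cell_mean <- function(m, i) {
    if (is.null(m)) NA_real_ else mean(m[i, ], na.rm = TRUE)
  }
  report <- data.frame(
    variant_key = rownames(matrix$presence)[keep],
    gene = unname(matrix$genes[keep]),
    clonality = as.character(labels[rownames(matrix$presence)[keep]]),
    mean_af = vapply(keep, function(i) cell_mean(matrix$af, i), numeric(1)),
    mean_ccf = vapply(keep, function(i) cell_mean(matrix$ccf, i), numeric(1)),
    stringsAsFactors = FALSE
  )
  frac <- if (nrow(report)) mean(report$clonality == "truncal") else NA_real_
  list(report = report, fraction_truncal = frac)
}
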