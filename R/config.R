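#' Pipeline configuration
#'
#' Bundles the tunable parameters shared by every stage of the pipeline.
#' Defaults reflect the conventions of multi-region biopsy studies: a DNA
#' concentration QC cut-off of 4 ng/uL, allele-frequency thresholds swept
#' from 0.01 to 0.55 in steps of 0.01, cancer-cell-fraction thresholds from
#' 0.90 to 1.00 in steps of 0.01, a progression-free-survival ratio of 1.3
#' defining clinical benefit, and a 0.05 significance level.
#'
#' @param qc_min_concentration Minimum DNA concentration (ng/uL) for a biopsy
#'   to pass quality control. Biopsies below it are dropped.
#' @param min_alt_reads Minimum alternate-read support for a call to count as
#'   "present". Defaults to 0: a call emitted by the upstream variant caller
#'   is trusted as-is.
#' @param af_grid Numeric vector of allele-frequency thresholds for the
#'   single-biopsy truncal prediction sweep.
#' @param ccf_grid Numeric vector of cancer-cell-fraction thresholds for the
#'   same sweep.
#' @param benefit_ratio_threshold PFS ratio at or above which a therapy is
#'   called beneficial.
#' @param alpha Significance level used by the saturation and comparison
#'   tests.
#' @param seed Optional integer seed forwarded to stochastic operations.
#'
#' @return An object of class `truncalis_config` (a validated list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$benefit_ratio_threshold
#' @export
pipeline_config <- function(qc_min_concentration = 4.0,
                            min_alt_reads = 0L,
                            af_grid = seq(0.01, 0.55, by = 0.01),
                            ccf_grid = seq(0.90, 1.00, by = 0.01),
                            benefit_ratio_threshold = 1.3,
                            alpha = 0.05,
                            seed = NULL) {
  stopifnot(length(af_grid) > 0, length(ccf_grid) > 0,
            all(diff(af_grid) > 0) || length(af_grid) == 1,
            all(diff(ccf_grid) > 0) || length(ccf_grid) == 1,
            qc_min_concentration >= 0, min_alt_reads >= 0,
            benefit_ratio_threshold > 0, alpha > 0)
  structure(list(
    qc_min_concentration = qc_min_concentration,
    min_alt_reads = as.integer(min_alt_reads),
    af_grid = af_grid,
    ccf_grid = ccf_grid,
    benefit_ratio_threshold = benefit_ratio_threshold,
    alpha = alpha,
    seed = seed
  ), class = "truncalis_config")
}

#' Read a configuration file
#'
#' Parses a minimal `key: value` text file (one pair per line, `#` comments
#' allowed) and overlays it on [pipeline_config()] defaults. Grid keys
#' (`af_grid_start`/`af_grid_stop`/`af_grid_step`, and the `ccf_grid_*`
#' analogues) are expanded with `seq()`.
#'
#' @param path Path to the configuration file.
#' @return A `truncalis_config` object.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- vapply(kv, length, 1L) < 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), ""))
  vals <- stats::setNames(as.list(suppressWarnings(as.numeric(vals))), keys)
  if (anyNA(unlist(vals))) {
    stop("non-numeric config value for: ",
         paste(keys[is.na(unlist(vals))], collapse = ", "))
  }
  grid_from <- function(prefix, default) {
    ks <- paste0(prefix, c("_start", "_stop", "_step"))
    if (all(ks %in% keys)) seq(vals[[ks[1]]], vals[[ks[2]]], by = vals[[ks[3]]]) else default
  }
  d <- pipeline_config()
  scalar <- function(key, default) if (key %in% keys) vals[[key]] else default
  pipeline_config(
    qc_min_concentration = scalar("qc_min_concentration", d$qc_min_concentration),
    min_alt_reads = scalar("min_alt_reads", d$min_alt_reads),
    af_grid = grid_from("af_grid", d$af_grid),
    ccf_grid = grid_from("ccf_grid", d$ccf_grid),
    benefit_ratio_threshold = scalar("benefit_ratio_threshold", d$benefit_ratio_threshold),
    alpha = scalar("alpha", d$alpha),
    seed = if ("seed" %in% keys) as.integer(vals[["seed"]]) else NULL
  )
}
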