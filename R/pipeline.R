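## End-to-end orchestration plus a thin command-line front end
## (`exec/truncalis`). Every stage writes plain TSV/JSON-free text outputs
## so results are diffable and re-loadable.

#' Run the full analysis pipeline
#'
#' QC-filters the input, classifies clonality per patient, summarizes
#' mutational load, runs the biopsy-saturation analysis (optionally per
#' gene panel), builds parsimony trees, sweeps AF/CCF thresholds against
#' the multi-biopsy truth, and evaluates clinical PFS ratios. Any stage
#' whose inputs are absent is skipped.
#'
#' @param calls Variant calls ([load_variant_table()] output or
#'   equivalent).
#' @param samples Biopsy sheet ([load_sample_table()] output or
#'   equivalent).
#' @param panels Optional list of [panel_definition()] objects.
#' @param clinical Optional clinical table ([load_clinical()] output).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, TSV outputs are written
#'   there.
#' @return List with `matrices`, `qc`, `clonality` (per-patient labels),
#'   `clonality_summary`, `load`, `profiles` (per panel), `increments`,
#'   `min_samples`, `trees`, `sweeps`, `outcomes`.
#' @export
run_pipeline <- function(calls, samples, panels = NULL, clinical = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  qc <- qc_filter(samples, calls, config)
  mats <- qc$matrices
  res <- list(qc = qc, matrices = mats)
  if (!length(mats)) {
    warning("no patient survived QC")
    return(res)
  }

  res$clonality <- lapply(mats, classify_clonality)
  res$clonality_summary <- cohort_clonality(res$clonality)
  res$load <- lapply(mats, mutational_load)

  panel_sets <- c(list(ALL = NULL), panels %||% list())
  res$profiles <- lapply(panel_sets, function(panel) {
    lapply(mats, function(pm) {
      if (!is.null(panel)) {
        pm <- filter_panel(pm, panel)
        if (attr(pm, "empty") || nrow(pm$presence) == 0) return(NULL)
      }
      saturation_profile(pm, if (is.null(panel)) "ALL" else panel$name)
    })
  })
  res$profiles <- lapply(res$profiles, function(x) Filter(Negate(is.null), x))
  res$increments <- lapply(Filter(function(x) length(x) >= 1, res$profiles),
                           increment_stats)
  res$min_samples <- lapply(
    Filter(function(x) length(x) >= 2, res$profiles),
    function(pr) list(
      unique = min_samples_required(pr, config$alpha, "unique"),
      ptv = min_samples_required(pr, config$alpha, "ptv")))

  res$trees <- lapply(mats, function(pm) {
    if (ncol(pm$presence) <= 8) build_tree(pm) else NULL
  })

  res$sweeps <- list(af = sweep_threshold(mats, "af", config$af_grid))
  has_ccf <- any(vapply(mats, function(m) !is.null(m$ccf), logical(1)))
  if (has_ccf) {
    res$sweeps$ccf <- sweep_threshold(mats, "ccf", config$ccf_grid)
  }

  if (!is.null(clinical)) {
    res$outcomes <- evaluate_outcomes(clinical,
                                      config$benefit_ratio_threshold)
    res$outcome_summary <- cohort_summary(res$outcomes)
  }

  if (!is.null(out_dir)) write_outputs(res, out_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_outputs <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(res$clonality)) {
    per_var <- do.call(rbind, lapply(names(res$clonality), function(p) {
      data.frame(patient_id = p, variant_key = names(res$clonality[[p]]),
                 clonality = as.character(res$clonality[[p]]),
                 stringsAsFactors = FALSE)
    }))
    tsv(per_var, "clonality.tsv")
    tsv(res$clonality_summary, "clonality_summary.tsv")
  }
  if (!is.null(res$profiles)) {
    long <- do.call(rbind, unlist(lapply(res$profiles, function(panel) {
      lapply(panel, function(pr) {
        cbind(patient_id = pr$patient_id, panel = pr$panel, pr$per_subset)
      })
    }), recursive = FALSE))
    if (!is.null(long)) tsv(long, "saturation.tsv")
  }
  if (!is.null(res$trees)) {
    nwk <- vapply(Filter(Negate(is.null), res$trees), to_newick, "")
    writeLines(nwk, file.path(dir, "trees.nwk"))
    assign_df <- do.call(rbind, lapply(Filter(Negate(is.null), res$trees),
                                       function(t) {
      cbind(patient_id = t$patient_id, t$assignments)
    }))
    if (!is.null(assign_df)) tsv(assign_df, "tree_assignments.tsv")
  }
  if (!is.null(res$sweeps)) {
    best <- do.call(rbind, lapply(res$sweeps, function(s) {
      cbind(metric = s$metric, s$by_group)
    }))
    tsv(best, "thresholds.tsv")
  }
  if (!is.null(res$outcomes)) tsv(res$outcomes, "outcomes.tsv")
  invisible(dir)
}

#' Command-line entry point
#'
#' Implements `truncalis <subcommand> --key value ...` with subcommands
#' `run` (full pipeline), `clonality`, `saturation`, `sweep`, `tree`,
#' `pfs` and `simulate`. See the package README for the option list; this
#' function is normally invoked through the installed `exec/truncalis`
#' script.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Exit status, invisibly (0 on success).
#' @export
truncalis_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: truncalis <run|clonality|saturation|sweep|tree|pfs|",
            "simulate> --variants V.tsv --samples S.tsv [--panel P.txt] ",
            "[--clinical C.tsv] [--config cfg.yml] [--seed N] --out DIR")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- list()
  kv <- args[-1]
  i <- 1
  while (i <= length(kv)) {
    if (!startsWith(kv[i], "--")) stop("unexpected argument: ", kv[i])
    opts[[substring(kv[i], 3)]] <- kv[i + 1]
    i <- i + 2
  }
  cfg <- if (!is.null(opts$config)) read_config(opts$config) else pipeline_config()
  out <- opts$out %||% "."

  if (cmd == "simulate") {
    sc <- sim_config(seed = as.integer(opts$seed %||% 1L))
    write_cohort(generate_cohort(sc), out)
    message("cohort written to ", out)
    return(invisible(0L))
  }
  if (cmd == "pfs") {
    clin <- load_clinical(opts$clinical)
    outc <- evaluate_outcomes(clin, cfg$benefit_ratio_threshold)
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    utils::write.table(outc, file.path(out, "outcomes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(0L))
  }

  calls <- load_variant_table(opts$variants, cfg)
  samples <- load_sample_table(opts$samples, cfg)
  panels <- if (!is.null(opts$panel)) list(load_panel(opts$panel)) else NULL
  clinical <- if (!is.null(opts$clinical)) load_clinical(opts$clinical)
  res <- run_pipeline(calls, samples, panels = panels, clinical = clinical,
                      config = cfg, out_dir = out)
  keep <- switch(cmd,
    run = TRUE,
    clonality = , saturation = , sweep = , tree = TRUE,
    stop("unknown subcommand: ", cmd))
  invisible(if (isTRUE(keep)) 0L else 1L)
}
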