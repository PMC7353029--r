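## Synthetic multi-region cohorts with known clonal structure. The
## generator states a world resembling a small multi-region biopsy study:
## 13 patients with 4 biopsies each; per patient a truncal clone carried by
## every biopsy at cancer cell fraction 1, shared subclones occupying
## proper subsets of >= 2 biopsies, and private subclones confined to one
## biopsy, with subclonal CCFs drawn from 0.1-0.6. Default variant counts
## (30 truncal / 20 shared / 75 private) put private mutations in the
## clear majority with roughly a quarter truncal, and the default mean
## depth of 128 reads matches routine exome coverage. Reads are sampled
## binomially: expected AF = purity * multiplicity * CCF /
## (purity * tumor_cn + 2 * (1 - purity)); depth is Poisson around the
## configured mean; a call is emitted iff at least one alternate read
## survives and the call is not suppressed by the false-negative rate.
## Clone geometry is membership-based, not spatial, and there is no
## sequencing-error or germline-contamination model.

#' Simulation configuration
#'
#' @param n_patients Number of patients.
#' @param n_biopsies Biopsies per patient (>= 2; shared subclones need
#'   >= 3).
#' @param n_truncal,n_shared_branch,n_private Variants per patient in each
#'   clonality class.
#' @param purity_range Biopsy purity drawn uniformly from this range,
#'   within `(0, 1]`.
#' @param depth Mean sequencing depth (reads per site, Poisson).
#' @param branch_ccf_range CCF range for shared and private subclones;
#'   truncal variants are fixed at CCF 1.
#' @param tumor_cn Local tumor total copy number applied to every variant.
#' @param multiplicity Mutated copies per carrying cell.
#' @param fn_rate Probability that a detectable call is dropped (emulates
#'   caller false negatives).
#' @param seed Optional integer seed; generation is bit-reproducible under
#'   a fixed seed.
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(n_patients = 13, n_biopsies = 4,
                       n_truncal = 30, n_shared_branch = 20, n_private = 75,
                       purity_range = c(0.5, 0.9), depth = 128,
                       branch_ccf_range = c(0.1, 0.6),
                       tumor_cn = 2, multiplicity = 1,
                       fn_rate = 0, seed = NULL) {
  stopifnot(n_patients >= 1, n_biopsies >= 2,
            n_truncal >= 0, n_shared_branch >= 0, n_private >= 0,
            depth >= 1,
            length(purity_range) == 2, purity_range[1] > 0,
            purity_range[2] <= 1, purity_range[1] <= purity_range[2],
            length(branch_ccf_range) == 2, branch_ccf_range[1] > 0,
            branch_ccf_range[2] <= 1,
            tumor_cn >= 1, multiplicity >= 1,
            fn_rate >= 0, fn_rate <= 1)
  if (n_shared_branch > 0 && n_biopsies < 3) {
    stop("shared branch variants need >= 3 biopsies ",
         "(a proper subset of >= 2 biopsies must exist)")
  }
  structure(as.list(environment()), class = "sim_config")
}

expected_af <- function(ccf, purity, tumor_cn, multiplicity) {
  purity * multiplicity * ccf / (purity * tumor_cn + 2 * (1 - purity))
}

#' Generate a synthetic multi-region cohort
#'
#' Emits per-biopsy somatic call tables in the exact dialect
#' [load_variant_table()] reads, a sample sheet, and the generating truth.
#'
#' @param config A [sim_config()].
#' @return List with `calls` (data.frame of emitted calls), `samples`
#'   (biopsy sheet incl. true purity), `truth` (per-variant true clonality,
#'   membership and CCF) and `config`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_patients = 2, seed = 1))
#' head(cohort$truth)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) {
    if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      old <- get(".Random.seed", envir = .GlobalEnv)
      on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
    }
    set.seed(config$seed)
  }
  calls <- list()
  truth <- list()
  samples <- list()
  n_var <- config$n_truncal + config$n_shared_branch + config$n_private
  for (p in seq_len(config$n_patients)) {
    pat <- sprintf("SP%02d", p)
    bx <- paste0("B", seq_len(config$n_biopsies))
    purity <- stats::runif(length(bx), config$purity_range[1],
                           config$purity_range[2])
    samples[[pat]] <- data.frame(
      patient_id = pat, biopsy_id = bx,
      dna_concentration = round(stats::runif(length(bx), 5, 60), 1),
      purity = purity, stringsAsFactors = FALSE)

    if (n_var == 0) next
    lab <- rep(c("truncal", "branch", "private"),
               c(config$n_truncal, config$n_shared_branch, config$n_private))
    b <- config$n_biopsies
    branch_sizes <- 2:(b - 1)  # proper subsets with >= 2 members
    members <- lapply(seq_len(n_var), function(v) {
      switch(lab[v],
        truncal = seq_len(b),
        branch = sort(sample.int(
          b, branch_sizes[sample.int(length(branch_sizes), 1)])),
        private = sample.int(b, 1))
    })
    ccf <- ifelse(lab == "truncal", 1,
                  stats::runif(n_var, config$branch_ccf_range[1],
                               config$branch_ccf_range[2]))
    pos <- 1000000L + seq_len(n_var)
    gene <- sprintf("GENE%04d", seq_len(n_var))
    key <- variant_key("1", pos, "A", "T")
    truth[[pat]] <- data.frame(
      patient_id = pat, variant_key = key, gene = gene,
      clonality = lab, ccf = ccf,
      biopsies = vapply(members, function(m) paste(bx[m], collapse = ","),
                        ""),
      stringsAsFactors = FALSE)

    for (v in seq_len(n_var)) {
      for (i in members[[v]]) {
        af <- expected_af(ccf[v], purity[i], config$tumor_cn,
                          config$multiplicity)
        depth_i <- stats::rpois(1, config$depth)
        if (depth_i == 0) next
        alt <- stats::rbinom(1, depth_i, af)
        if (alt < 1) next
        if (config$fn_rate > 0 && stats::runif(1) < config$fn_rate) next
        calls[[length(calls) + 1L]] <- data.frame(
          patient_id = pat, biopsy_id = bx[i], gene = gene[v],
          chrom = "1", pos = pos[v], ref = "A", alt = "T",
          alt_count = alt, ref_count = depth_i - alt,
          variant_class = "Missense_Mutation", is_nss = TRUE,
          purity = purity[i], tumor_cn = config$tumor_cn,
          multiplicity = config$multiplicity,
          variant_key = key[v], stringsAsFactors = FALSE)
      }
    }
  }
  empty_calls <- data.frame(
    patient_id = character(), biopsy_id = character(), gene = character(),
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), alt_count = integer(), ref_count = integer(),
    variant_class = character(), is_nss = logical(), purity = numeric(),
    tumor_cn = numeric(), multiplicity = numeric(),
    variant_key = character(), stringsAsFactors = FALSE)
  list(calls = if (length(calls)) do.call(rbind, calls) else empty_calls,
       samples = do.call(rbind, c(samples, list(make.row.names = FALSE))),
       truth = if (length(truth)) {
         do.call(rbind, c(truth, list(make.row.names = FALSE)))
       } else {
         NULL
       },
       config = config)
}

#' Write a synthetic cohort to disk
#'
#' Emits `variants.tsv`, `samples.tsv` and `truth.tsv` in the dialects the
#' loaders read.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(cohort$calls[setdiff(names(cohort$calls), "variant_key")],
      "variants.tsv")
  tsv(cohort$samples, "samples.tsv")
  if (!is.null(cohort$truth)) tsv(cohort$truth, "truth.tsv")
  invisible(dir)
}

#' Score pipeline labels against simulation truth
#'
#' Truncal-versus-not confusion matrix of the pipeline's clonality labels
#' for one patient against the generating truth.
#'
#' @param labels Factor from [classify_clonality()], named by variant key.
#' @param truth Truth data.frame (rows for one patient) from
#'   [generate_cohort()].
#' @return List with `confusion` (2x2 matrix), `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
truth_accuracy <- function(labels, truth) {
  if (!setequal(names(labels), truth$variant_key)) {
    stop("label and truth variant sets differ")
  }
  truth_truncal <- truth$clonality[match(names(labels),
                                         truth$variant_key)] == "truncal"
  pred_truncal <- labels == "truncal"
  confusion <- table(
    predicted = factor(pred_truncal, levels = c(TRUE, FALSE),
                       labels = c("truncal", "not_truncal")),
    truth = factor(truth_truncal, levels = c(TRUE, FALSE),
                   labels = c("truncal", "not_truncal")))
  tp <- confusion["truncal", "truncal"]
  tn <- confusion["not_truncal", "not_truncal"]
  list(confusion = confusion,
       accuracy = (tp + tn) / length(labels),
       sensitivity = if (sum(truth_truncal)) {
         tp / sum(truth_truncal)
       } else {
         NA_real_
       },
       specificity = if (sum(!truth_truncal)) {
         tn / sum(!truth_truncal)
       } else {
         NA_real_
       })
}
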