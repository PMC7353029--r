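## Data model and readers. Variant tables arrive as MAF-like TSV, one row per
## somatic call per biopsy; coordinates are 1-based fully closed. A variant's
## identity is (chrom, pos, ref, alt) -- the gene symbol is annotation only
## and deliberately not part of the key.

VARIANT_COLUMNS <- c("patient_id", "biopsy_id", "gene", "chrom", "pos",
                     "ref", "alt", "alt_count", "ref_count", "variant_class")

## Oncotator-style classes counted as non-synonymous somatic when the table
## carries no explicit is_nss column.
NSS_CLASSES <- c(
  "MISSENSE_MUTATION", "MISSENSE", "NONSENSE_MUTATION", "NONSENSE",
  "NONSTOP_MUTATION", "SPLICE_SITE", "TRANSLATION_START_SITE",
  "FRAME_SHIFT_INS", "FRAME_SHIFT_DEL", "IN_FRAME_INS", "IN_FRAME_DEL",
  "START_CODON_SNP", "DE_NOVO_START_OUT_FRAME"
)

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Load a per-biopsy somatic variant table
#'
#' Reads a tab-separated MAF-like table with one row per observed call.
#' Mandatory columns: `patient_id`, `biopsy_id`, `gene`, `chrom`, `pos`,
#' `ref`, `alt`, `alt_count`, `ref_count`, `variant_class`. An `is_nss`
#' column (logical, or 0/1) is honoured if present; otherwise it is derived
#' from `variant_class` against the usual non-synonymous annotation classes.
#' Unknown columns are preserved. Rows that fail to parse (non-numeric
#' counts, negative counts, zero total depth, `ref == alt`) are dropped and
#' reported through a warning plus a `"row_errors"` attribute holding the
#' offending line numbers.
#'
#' @param path Path to the TSV file.
#' @param config A [pipeline_config()] (reserved; parsing itself is
#'   config-free).
#' @return A data.frame of calls with an added `variant_key` column and an
#'   `is_nss` logical column; attribute `row_errors` lists skipped rows.
#' @export
load_variant_table <- function(path, config = pipeline_config()) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(VARIANT_COLUMNS, names(df))
  if (length(missing)) {
    stop("missing column: ", paste(missing, collapse = ", "))
  }
  df$pos <- suppressWarnings(as.integer(df$pos))
  df$alt_count <- suppressWarnings(as.integer(df$alt_count))
  df$ref_count <- suppressWarnings(as.integer(df$ref_count))
  if ("is_nss" %in% names(df)) {
    df$is_nss <- toupper(trimws(df$is_nss)) %in% c("TRUE", "T", "1", "YES")
  } else {
    df$is_nss <- toupper(df$variant_class) %in% NSS_CLASSES
  }
  bad <- is.na(df$pos) | is.na(df$alt_count) | is.na(df$ref_count) |
    df$alt_count < 0 | df$ref_count < 0 |
    (df$alt_count + df$ref_count) == 0 | df$ref == df$alt
  row_errors <- which(bad)
  if (length(row_errors)) {
    warning(sprintf("%d malformed row(s) dropped (data lines: %s)",
                    length(row_errors),
                    paste(utils::head(row_errors, 20), collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
  }
  df$gene <- toupper(df$gene)
  df$variant_key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  rownames(df) <- NULL
  attr(df, "row_errors") <- row_errors
  df
}

#' Load a biopsy sample sheet
#'
#' TSV with columns `patient_id`, `biopsy_id` and optionally
#' `dna_concentration` (ng/uL). The QC flag is derived: a biopsy fails when
#' its concentration is present and below the configured minimum.
#'
#' @param path Path to the TSV file.
#' @param config A [pipeline_config()]; supplies `qc_min_concentration`.
#' @return data.frame with a logical `qc_pass` column.
#' @export
load_sample_table <- function(path, config = pipeline_config()) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("patient_id", "biopsy_id")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("missing column: ", paste(missing, collapse = ", "))
  if (!"dna_concentration" %in% names(df)) df$dna_concentration <- NA_real_
  df$dna_concentration <- as.numeric(df$dna_concentration)
  df$qc_pass <- is.na(df$dna_concentration) |
    df$dna_concentration >= config$qc_min_concentration
  df
}

#' Load a gene panel
#'
#' Plain text, one HGNC-style symbol per line; blanks and `#` comments are
#' ignored. Symbols are uppercased and deduplicated (with a warning when
#' duplicates are found).
#'
#' @param path Path to the panel file.
#' @param name Panel name; defaults to the file name without extension.
#' @return A `panel_definition` object: list with `name` and `genes`.
#' @export
load_panel <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  genes <- toupper(lines[nzchar(lines)])
  if (!length(genes)) stop("empty panel file: ", path)
  if (anyDuplicated(genes)) {
    warning("duplicate gene symbols deduplicated in panel: ", path)
    genes <- unique(genes)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  panel_definition(name, genes)
}

#' Construct a gene panel definition
#'
#' @param name Panel name.
#' @param genes Character vector of gene symbols (uppercased, deduplicated).
#' @return A `panel_definition` object.
#' @export
panel_definition <- function(name, genes) {
  genes <- unique(toupper(as.character(genes)))
  stopifnot(is.character(name), length(name) == 1, length(genes) >= 1)
  structure(list(name = name, genes = genes), class = "panel_definition")
}

#' Load a clinical outcome table
#'
#' TSV with columns `patient_id`, `pfs_prior_months` (PFS on the most recent
#' prior therapy) and `pfs_tdt_months` (PFS on the truncal-mutation-directed
#' therapy). Rows with non-numeric or non-positive PFS are dropped and
#' reported; duplicate patients are deduplicated (first row wins) with a
#' warning.
#'
#' @param path Path to the TSV file.
#' @return data.frame of clinical records; attribute `row_errors` lists
#'   skipped rows.
#' @export
load_clinical <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("patient_id", "pfs_prior_months", "pfs_tdt_months")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("missing column: ", paste(missing, collapse = ", "))
  if (!nrow(df)) stop("empty clinical file: ", path)
  df$pfs_prior_months <- suppressWarnings(as.numeric(df$pfs_prior_months))
  df$pfs_tdt_months <- suppressWarnings(as.numeric(df$pfs_tdt_months))
  bad <- is.na(df$pfs_prior_months) | is.na(df$pfs_tdt_months) |
    df$pfs_prior_months <= 0 | df$pfs_tdt_months <= 0
  row_errors <- which(bad)
  if (length(row_errors)) {
    warning(sprintf("%d clinical row(s) dropped (lines: %s)",
                    length(row_errors), paste(row_errors, collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
  }
  if (anyDuplicated(df$patient_id)) {
    warning("duplicate patient_id in clinical table; keeping first occurrence")
    df <- df[!duplicated(df$patient_id), , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "row_errors") <- row_errors
  df
}

#' Construct a presence matrix
#'
#' The substrate of all clonality and saturation computations: one patient's
#' binary variant-by-biopsy matrix, with optional per-cell allele frequency
#' and cancer cell fraction (NA where the variant is absent) and a per-row
#' gene annotation.
#'
#' @param patient_id Patient identifier.
#' @param presence Logical matrix, rows = variant identity keys, columns =
#'   QC-passed biopsy ids (both named). Every row must have at least one
#'   `TRUE` cell.
#' @param af,ccf Optional numeric matrices with the same dimnames; cells
#'   where `presence` is `FALSE` must be `NA`.
#' @param genes Optional character vector of gene symbols, one per row.
#' @return A `presence_matrix` object.
#' @export
presence_matrix <- function(patient_id, presence, af = NULL, ccf = NULL,
                            genes = NULL) {
  stopifnot(is.matrix(presence), is.logical(presence),
            !is.null(colnames(presence)))
  if (is.null(rownames(presence))) {
    if (nrow(presence) > 0) stop("presence matrix needs variant rownames")
    rownames(presence) <- character(0)
  }
  if (nrow(presence) > 0 && any(rowSums(presence) == 0)) {
    stop("presence matrix has all-absent variant row(s)")
  }
  check_overlay <- function(m, what) {
    if (is.null(m)) return(NULL)
    stopifnot(is.matrix(m), all(dim(m) == dim(presence)))
    dimnames(m) <- dimnames(presence)
    if (any(!is.na(m) & !presence)) {
      stop(what, " defined in absent cell(s)")
    }
    m
  }
  af <- check_overlay(af, "AF")
  ccf <- check_overlay(ccf, "CCF")
  if (!is.null(genes)) {
    stopifnot(length(genes) == nrow(presence))
    genes <- toupper(as.character(genes))
    names(genes) <- rownames(presence)
  }
  structure(list(patient_id = patient_id,
                 biopsy_ids = colnames(presence),
                 variant_keys = rownames(presence),
                 presence = presence, af = af, ccf = ccf, genes = genes),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: patient %s, %d variants x %d biopsies\n",
              x$patient_id, nrow(x$presence), ncol(x$presence)))
  invisible(x)
}

#' @export
dim.presence_matrix <- function(x) dim(x$presence)

#' Apply quality control and build per-patient presence matrices
#'
#' Biopsies whose DNA concentration falls below the configured minimum are
#' dropped together with their calls; patients left with fewer than two
#' QC-passed biopsies are excluded from clonality analysis and reported. A
#' presence cell is `TRUE` iff a non-synonymous somatic call with
#' `alt_count >= min_alt_reads` exists for that variant in that biopsy.
#' Applying the filter twice is a no-op (idempotent).
#'
#' @param samples data.frame as returned by [load_sample_table()] (or with
#'   columns `patient_id`, `biopsy_id`, optional `dna_concentration`,
#'   optional `qc_pass`).
#' @param calls data.frame of calls as returned by [load_variant_table()].
#' @param config A [pipeline_config()].
#' @return List with `matrices` (named list of `presence_matrix`, one per
#'   retained patient), `excluded_patients` (data.frame with reasons) and
#'   `failed_biopsies` (data.frame of dropped biopsies).
#' @export
qc_filter <- function(samples, calls, config = pipeline_config()) {
  stopifnot(all(c("patient_id", "biopsy_id") %in% names(samples)))
  if (!"qc_pass" %in% names(samples)) {
    conc <- if ("dna_concentration" %in% names(samples)) {
      as.numeric(samples$dna_concentration)
    } else rep(NA_real_, nrow(samples))
    samples$qc_pass <- is.na(conc) | conc >= config$qc_min_concentration
  }
  known <- paste(samples$patient_id, samples$biopsy_id)
  seen <- paste(calls$patient_id, calls$biopsy_id)
  unknown <- setdiff(unique(seen), known)
  if (length(unknown)) {
    stop("calls reference unknown biopsy: ", paste(unknown, collapse = ", "))
  }

  failed <- samples[!samples$qc_pass, c("patient_id", "biopsy_id"), drop = FALSE]
  passed <- samples[samples$qc_pass, , drop = FALSE]
  n_pass <- table(passed$patient_id)
  all_pat <- unique(samples$patient_id)
  keep_pat <- names(n_pass)[n_pass >= 2]
  excluded <- setdiff(all_pat, keep_pat)
  excluded_df <- data.frame(
    patient_id = excluded,
    n_qc_passed = as.integer(n_pass[excluded]),
    stringsAsFactors = FALSE
  )
  excluded_df$n_qc_passed[is.na(excluded_df$n_qc_passed)] <- 0L
  excluded_df$reason <- rep("fewer than 2 QC-passed biopsies",
                            nrow(excluded_df))

  matrices <- list()
  for (pat in keep_pat) {
    bx <- sort(passed$biopsy_id[passed$patient_id == pat])
    pc <- calls[calls$patient_id == pat & calls$biopsy_id %in% bx &
                  calls$is_nss & calls$alt_count >= config$min_alt_reads,
                , drop = FALSE]
    if (!nrow(pc)) next
    keys <- sort(unique(pc$variant_key))
    pres <- matrix(FALSE, length(keys), length(bx),
                   dimnames = list(keys, bx))
    afm <- matrix(NA_real_, length(keys), length(bx),
                  dimnames = list(keys, bx))
    af_val <- pc$alt_count / (pc$alt_count + pc$ref_count)
    ## per-call CCF: taken verbatim from a `ccf` column when provided,
    ## otherwise computed from purity/copy-number annotations when present;
    ## patients with neither simply carry no CCF overlay
    if (!"ccf" %in% names(pc) && "purity" %in% names(pc)) {
      cn <- if ("tumor_cn" %in% names(pc)) as.numeric(pc$tumor_cn) else 2
      mult <- if ("multiplicity" %in% names(pc)) {
        as.numeric(pc$multiplicity)
      } else 1
      pc$ccf <- as.numeric(estimate_ccf(af_val, as.numeric(pc$purity),
                                        cn, mult))
    }
    idx <- cbind(match(pc$variant_key, keys), match(pc$biopsy_id, bx))
    pres[idx] <- TRUE
    afm[idx] <- af_val
    ccfm <- NULL
    if ("ccf" %in% names(pc) && any(!is.na(suppressWarnings(as.numeric(pc$ccf))))) {
      ccfm <- matrix(NA_real_, length(keys), length(bx),
                     dimnames = list(keys, bx))
      ccfm[idx] <- suppressWarnings(as.numeric(pc$ccf))
    }
    genes <- pc$gene[match(keys, pc$variant_key)]
    matrices[[pat]] <- presence_matrix(pat, pres, af = afm, ccf = ccfm,
                                       genes = genes)
  }
  list(matrices = matrices, excluded_patients = excluded_df,
       failed_biopsies = failed)
}

#' Write / read a presence matrix as TSV
#'
#' The on-disk layout is long format: one row per present cell with columns
#' `patient_id`, `variant_key`, `gene`, `biopsy_id`, `af`, `ccf`. Numeric
#' values are written with 17 significant digits so that a write/read
#' round-trip is bit-exact.
#'
#' @param x A `presence_matrix`.
#' @param path Output file path.
#' @return `write_presence_matrix` returns `path` invisibly;
#'   `read_presence_matrix` returns a `presence_matrix`.
#' @export
write_presence_matrix <- function(x, path) {
  idx <- which(x$presence, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]  # stable row order
  num <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  df <- data.frame(
    patient_id = x$patient_id,
    variant_key = rownames(x$presence)[idx[, 1]],
    gene = if (is.null(x$genes)) "NA" else unname(x$genes[idx[, 1]]),
    biopsy_id = colnames(x$presence)[idx[, 2]],
    af = if (is.null(x$af)) "NA" else num(x$af[idx]),
    ccf = if (is.null(x$ccf)) "NA" else num(x$ccf[idx]),
    stringsAsFactors = FALSE
  )
  ## biopsy columns are recorded in a header comment so absent-everywhere
  ## biopsies survive the round trip
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#biopsy_ids\t", paste(x$biopsy_ids, collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  stopifnot(startsWith(header, "#biopsy_ids\t"))
  bx <- strsplit(sub("^#biopsy_ids\t", "", header), "\t")[[1]]
  df <- utils::read.delim(path, sep = "\t", skip = 1L, header = TRUE,
                          colClasses = "character", stringsAsFactors = FALSE)
  keys <- unique(df$variant_key)
  pres <- matrix(FALSE, length(keys), length(bx), dimnames = list(keys, bx))
  afm <- matrix(NA_real_, length(keys), length(bx), dimnames = list(keys, bx))
  ccfm <- matrix(NA_real_, length(keys), length(bx), dimnames = list(keys, bx))
  idx <- cbind(match(df$variant_key, keys), match(df$biopsy_id, bx))
  pres[idx] <- TRUE
  afm[idx] <- suppressWarnings(as.numeric(df$af))
  ccfm[idx] <- suppressWarnings(as.numeric(df$ccf))
  genes <- df$gene[match(keys, df$variant_key)]
  if (all(is.na(genes) | genes == "NA")) genes <- NULL
  if (all(is.na(afm))) afm <- NULL
  if (all(is.na(ccfm))) ccfm <- NULL
  presence_matrix(df$patient_id[1], pres, af = afm, ccf = ccfm, genes = genes)
}
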