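# Shared fixtures, built in code.

# F1: 4 biopsies; v1 truncal, v2 branch (B1-B3), v3 private (B1)
f1_matrix <- function() {
  pres <- matrix(c(TRUE, TRUE, TRUE, TRUE,
                   TRUE, TRUE, TRUE, FALSE,
                   TRUE, FALSE, FALSE, FALSE), 3, 4, byrow = TRUE,
                 dimnames = list(c("v1", "v2", "v3"), paste0("B", 1:4)))
  presence_matrix("F1", pres,
                  genes = c("EGFR", "TP53", "TTN"))
}

# random presence matrix; every row has >= 1 present cell
random_presence_matrix <- function(n_bx, n_var, p = 0.5,
                                   patient = "RP") {
  pres <- matrix(stats::runif(n_var * n_bx) < p, n_var, n_bx,
                 dimnames = list(sprintf("v%03d", seq_len(n_var)),
                                 paste0("B", seq_len(n_bx))))
  empty <- rowSums(pres) == 0
  for (i in which(empty)) pres[i, sample.int(n_bx, 1)] <- TRUE
  presence_matrix(patient, pres)
}

# compatible (perfect-phylogeny) matrix: draw a random rooted binary tree
# over the biopsies and give each variant the leaf set of a random edge's
# clade, always including one truncal variant so the trunk is non-trivial
random_compatible_matrix <- function(n_bx, n_var, patient = "CP") {
  stopifnot(n_var >= 1)
  # random nested topology over 1..n_bx
  topo <- 1L
  for (i in seq_len(n_bx)[-1]) {
    # insert leaf i at a uniformly chosen position by random descent
    attach_random <- function(t) {
      if (!is.list(t) || stats::runif(1) < 0.4) return(list(t, i))
      if (stats::runif(1) < 0.5) list(attach_random(t[[1]]), t[[2]])
      else list(t[[1]], attach_random(t[[2]]))
    }
    topo <- attach_random(topo)
  }
  clades <- list()
  collect <- function(t) {
    lv <- if (!is.list(t)) t else c(collect(t[[1]]), collect(t[[2]]))
    clades[[length(clades) + 1L]] <<- lv
    lv
  }
  collect(topo)
  clades <- unique(clades)
  pres <- matrix(FALSE, n_var, n_bx,
                 dimnames = list(sprintf("v%03d", seq_len(n_var)),
                                 paste0("B", seq_len(n_bx))))
  pres[1, ] <- TRUE  # guaranteed truncal variant
  if (n_var > 1) {
    for (v in 2:n_var) {
      pres[v, clades[[sample.int(length(clades), 1)]]] <- TRUE
    }
  }
  presence_matrix(patient, pres)
}

# small deterministic cohort of presence matrices
fixture_cohort <- function(n_patients = 6, n_bx = 4, n_var = 30,
                           seed = 42) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", .GlobalEnv)) .GlobalEnv$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    code
  }
  withr_seed(lapply(seq_len(n_patients), function(i) {
    random_presence_matrix(n_bx, n_var, patient = sprintf("P%02d", i))
  }))
}
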