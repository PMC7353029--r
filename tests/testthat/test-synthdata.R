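test_that("configuration validation", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_biopsies = 1))
  expect_error(sim_config(purity_range = c(0, 0.5)))
  expect_error(sim_config(fn_rate = 1.5))
  # shared subclones need a proper subset of >= 2 biopsies to live in
  expect_error(sim_config(n_biopsies = 2, n_shared_branch = 5),
               "proper subset")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_patients = 2, n_truncal = 5, n_shared_branch = 3,
                    n_private = 8, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$calls, b$calls)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
})

test_that("degenerate regimes: fn_rate 1 and noise-free recovery", {
  empty <- generate_cohort(sim_config(n_patients = 1, fn_rate = 1,
                                      seed = 1))
  expect_equal(nrow(empty$calls), 0)

  cfg <- sim_config(n_patients = 3, n_truncal = 5, n_shared_branch = 0,
                    n_private = 0, fn_rate = 0, depth = 10000,
                    purity_range = c(1, 1), seed = 77)
  cohort <- generate_cohort(cfg)
  qc <- qc_filter(cohort$samples, cohort$calls)
  expect_length(qc$matrices, 3)
  for (pm in qc$matrices) {
    labs <- classify_clonality(pm)
    expect_equal(unname(attr(labs, "counts")), c(5L, 0L, 0L))
  }
})

test_that("truth scoring and end-to-end label recovery", {
  cfg <- sim_config(n_patients = 4, n_truncal = 10, n_shared_branch = 8,
                    n_private = 20, fn_rate = 0, depth = 5000,
                    branch_ccf_range = c(0.3, 0.6), seed = 99)
  cohort <- generate_cohort(cfg)
  qc <- qc_filter(cohort$samples, cohort$calls)
  for (pat in names(qc$matrices)) {
    labs <- classify_clonality(qc$matrices[[pat]])
    acc <- truth_accuracy(labs, cohort$truth[cohort$truth$patient_id == pat, ])
    expect_equal(acc$accuracy, 1.0)
    expect_equal(acc$sensitivity, 1.0)
    expect_equal(acc$specificity, 1.0)
  }
  # mismatched variant sets refuse to score
  labs <- classify_clonality(qc$matrices[[1]])
  expect_error(truth_accuracy(labs[-1],
                              cohort$truth[cohort$truth$patient_id ==
                                             names(qc$matrices)[1], ]),
               "differ")
  # half-truncal truth, all predicted truncal -> accuracy 0.5
  truth <- data.frame(patient_id = "X",
                      variant_key = paste0("k", 1:4),
                      clonality = c("truncal", "truncal", "private",
                                    "branch"),
                      stringsAsFactors = FALSE)
  labs <- structure(factor(rep("truncal", 4),
                           levels = c("truncal", "branch", "private")),
                    names = paste0("k", 1:4))
  expect_equal(truth_accuracy(labs, truth)$accuracy, 0.5)
})

test_that("expected allele frequency of truncal variants is purity/2", {
  # >= 1000 truncal sites at depth 100, purity p, cn 2, multiplicity 1
  p <- 0.7
  cfg <- sim_config(n_patients = 1, n_biopsies = 2, n_truncal = 600,
                    n_shared_branch = 0, n_private = 0,
                    purity_range = c(p, p), depth = 100, seed = 11)
  cohort <- generate_cohort(cfg)
  af <- cohort$calls$alt_count /
    (cohort$calls$alt_count + cohort$calls$ref_count)
  expect_gte(length(af), 1000)
  se <- sd(af) / sqrt(length(af))
  expect_lt(abs(mean(af) - p / 2), 3 * se)
})

test_that("CCF recovery from generated reads: MAE < 0.02 at depth 1e4", {
  cfg <- sim_config(n_patients = 2, n_truncal = 20, n_shared_branch = 15,
                    n_private = 40, depth = 1e4, fn_rate = 0, seed = 13)
  cohort <- generate_cohort(cfg)
  af <- cohort$calls$alt_count /
    (cohort$calls$alt_count + cohort$calls$ref_count)
  ccf_hat <- as.numeric(estimate_ccf(af, cohort$calls$purity,
                                     cohort$calls$tumor_cn,
                                     cohort$calls$multiplicity))
  key <- paste(cohort$calls$patient_id, cohort$calls$variant_key)
  truth_ccf <- cohort$truth$ccf[match(key, paste(cohort$truth$patient_id,
                                                 cohort$truth$variant_key))]
  expect_lt(mean(abs(ccf_hat - truth_ccf)), 0.02)
})

test_that("higher false-negative rates only lower avg_ptv", {
  rates <- c(0, 0.2, 0.5)
  mean_ptv <- sapply(rates, function(fr) {
    vals <- sapply(1:4, function(s) {
      cfg <- sim_config(n_patients = 1, n_truncal = 15, n_shared_branch = 10,
                        n_private = 20, fn_rate = fr, depth = 200,
                        seed = 1000 + s)
      cohort <- generate_cohort(cfg)
      qc <- qc_filter(cohort$samples, cohort$calls)
      if (!length(qc$matrices)) return(0)
      mean(saturation_profile(qc$matrices[[1]])$summary$avg_ptv)
    })
    mean(vals)
  })
  expect_true(all(diff(mean_ptv) < 0))
})

test_that("written cohorts re-load through the standard readers", {
  cfg <- sim_config(n_patients = 2, n_truncal = 4, n_shared_branch = 3,
                    n_private = 5, seed = 3)
  cohort <- generate_cohort(cfg)
  dir <- tempfile()
  write_cohort(cohort, dir)
  calls <- load_variant_table(file.path(dir, "variants.tsv"))
  samples <- load_sample_table(file.path(dir, "samples.tsv"))
  expect_equal(nrow(calls), nrow(cohort$calls))
  expect_equal(sort(unique(calls$patient_id)), c("SP01", "SP02"))
  expect_true(all(samples$qc_pass))
  qc <- qc_filter(samples, calls)
  expect_length(qc$matrices, 2)
})
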