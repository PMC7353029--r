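test_that("AF and CCF estimators match hand arithmetic", {
  expect_equal(compute_af(7, 93), 0.07)
  expect_equal(compute_af(0, 50), 0)
  expect_equal(compute_af(50, 0), 1)
  expect_error(compute_af(0, 0), "zero")

  expect_equal(as.numeric(estimate_ccf(0.5, purity = 1)), 1)
  expect_equal(as.numeric(estimate_ccf(0.25, purity = 0.5)), 1)
  expect_equal(as.numeric(estimate_ccf(0.2, purity = 0.8, tumor_cn = 3)),
               0.7)
  # clipping is counted, not silent
  out <- estimate_ccf(c(0.9, 0.2), purity = 0.5)  # raw 3.6 and 0.8
  expect_equal(as.numeric(out), c(1, 0.8))
  expect_equal(attr(out, "n_clipped"), 1L)
  expect_error(estimate_ccf(0.5, purity = 0), "purity")
  expect_error(estimate_ccf(0.5, purity = 0.5, multiplicity = 0),
               "multiplicity")
})

test_that("threshold classification uses an inclusive boundary", {
  vals <- c(a = 0.4, b = 0.13, c = 0.05)
  expect_equal(unname(classify_by_threshold(vals, 0.13)),
               c("truncal", "truncal", "branch"), ignore_attr = TRUE)
  expect_true(all(classify_by_threshold(vals, 0) == "truncal"))
  expect_true(all(classify_by_threshold(vals, 0.41) == "branch"))
  expect_equal(attr(classify_by_threshold(vals, 0.1), "rule"), ">=")
})

# one patient, 3 biopsies; v1 truncal with high AF everywhere, v2 branch,
# v3 private with low AF
sweep_fixture <- function() {
  pres <- matrix(c(TRUE, TRUE, TRUE,
                   TRUE, TRUE, FALSE,
                   TRUE, FALSE, FALSE), 3, 3, byrow = TRUE,
                 dimnames = list(c("v1", "v2", "v3"), paste0("B", 1:3)))
  af <- matrix(NA_real_, 3, 3, dimnames = dimnames(pres))
  af[1, ] <- 0.40
  af[2, 1:2] <- 0.20
  af[3, 1] <- 0.05
  presence_matrix("SW", pres, af = af)
}

test_that("sweep accuracy follows the per-biopsy averaging formula", {
  pm <- sweep_fixture()
  sw <- sweep_threshold(list(SW = pm), "af", grid = 0.13)
  # at 0.13: B1 calls v1,v2 truncal (v2 wrong), v3 branch -> 2/3;
  # B2 calls v1,v2 truncal -> 1/2; B3 calls v1 truncal -> 1/1
  expect_equal(unname(sw$accuracy[1, 1]), mean(c(2 / 3, 1 / 2, 1)))

  sw <- sweep_threshold(list(SW = pm), "af", grid = seq(0.01, 0.55, 0.01))
  expect_equal(sw$by_group$best_accuracy, 1)
  # smallest grid value separating 0.20 from 0.40
  expect_equal(sw$by_group$best_threshold, 0.21)
})

test_that("degenerate sweeps behave", {
  # all variants truncal at metric 1.0: perfect at every threshold <= 1
  pres <- matrix(TRUE, 2, 2, dimnames = list(c("v1", "v2"), c("B1", "B2")))
  af <- matrix(1, 2, 2, dimnames = dimnames(pres))
  sw <- sweep_threshold(list(T = presence_matrix("T", pres, af = af)),
                        "af", grid = c(0.1, 0.5, 1.0))
  expect_true(all(sw$accuracy == 1))
  expect_equal(sw$by_group$best_threshold, 0.1)

  # patients without CCF overlays are skipped and reported (not fatal when
  # at least one patient remains; fatal when none does)
  pm_no_ccf <- sweep_fixture()
  expect_error(sweep_threshold(list(P07 = pm_no_ccf), "ccf",
                               grid = seq(0.9, 1, 0.01)),
               "no patient with usable CCF")
})

test_that("duplicating every variant leaves the accuracy unchanged", {
  pm <- sweep_fixture()
  pres2 <- rbind(pm$presence, pm$presence)
  af2 <- rbind(pm$af, pm$af)
  rownames(pres2) <- rownames(af2) <- paste0("v", 1:6)
  pm2 <- presence_matrix("SW", pres2, af = af2)
  grid <- seq(0.01, 0.55, 0.01)
  sw1 <- sweep_threshold(list(a = pm), "af", grid)
  sw2 <- sweep_threshold(list(a = pm2), "af", grid)
  expect_equal(sw2$accuracy, sw1$accuracy)
})

test_that("metric comparison pairs patients and tests the difference", {
  pm <- sweep_fixture()
  grid <- seq(0.01, 0.55, 0.01)
  sw <- sweep_threshold(list(SW = pm), "af", grid)
  cmp <- compare_metrics(sw, sw)
  expect_equal(cmp$mean_improvement, 0)
  expect_true(is.na(cmp$p_value))  # single patient: difference only

  # identical metrics over several patients: difference 0, p = 1
  set.seed(31)
  mats <- lapply(1:5, function(i) {
    pm <- random_presence_matrix(3, 10, patient = paste0("P", i))
    af <- matrix(NA_real_, 10, 3, dimnames = dimnames(pm$presence))
    af[pm$presence] <- runif(sum(pm$presence))
    presence_matrix(pm$patient_id, pm$presence, af = af)
  })
  names(mats) <- paste0("P", 1:5)
  sw <- sweep_threshold(mats, "af", grid)
  cmp <- compare_metrics(sw, sw)
  expect_equal(cmp$mean_improvement, 0)
  expect_equal(cmp$p_value, 1)

  sw_sub <- sweep_threshold(mats[1:3], "af", grid)
  expect_error(compare_metrics(sw, sw_sub), "unpaired")
})

test_that("grouping by cancer type produces per-group rows", {
  set.seed(32)
  mats <- lapply(1:4, function(i) {
    pm <- random_presence_matrix(3, 8, patient = paste0("P", i))
    af <- matrix(NA_real_, 8, 3, dimnames = dimnames(pm$presence))
    af[pm$presence] <- runif(sum(pm$presence))
    presence_matrix(pm$patient_id, pm$presence, af = af)
  })
  names(mats) <- paste0("P", 1:4)
  groups <- c(P1 = "NSCLC", P2 = "NSCLC", P3 = "OV", P4 = "OV")
  sw <- sweep_threshold(mats, "af", seq(0.1, 0.5, 0.1),
                        grouping = "cancer_type", groups = groups)
  expect_setequal(sw$by_group$group, c("NSCLC", "OV"))
  expect_equal(sw$by_group$n_patients, c(2L, 2L))
  expect_error(sweep_threshold(mats, "af", 0.1, grouping = "cancer_type"),
               "mapping")
})
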