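test_that("clonality definitions on the F1 fixture and edge cases", {
  labs <- classify_clonality(f1_matrix())
  expect_equal(as.character(labs), c("truncal", "branch", "private"),
               ignore_attr = TRUE)
  expect_equal(clonality_proportions(labs),
               c(truncal = 1 / 3, branch = 1 / 3, private = 1 / 3))

  # saturated matrix: everything truncal
  pres <- matrix(TRUE, 4, 3, dimnames = list(paste0("v", 1:4),
                                             paste0("B", 1:3)))
  labs <- classify_clonality(presence_matrix("S", pres))
  expect_equal(attr(labs, "counts"),
               c(truncal = 4L, branch = 0L, private = 0L))
  expect_equal(clonality_proportions(labs),
               c(truncal = 1, branch = 0, private = 0))

  # 2-biopsy patient: truncal = both, branch class empty by construction
  pres <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2, byrow = TRUE,
                 dimnames = list(c("akt1", "v2"), c("B1", "B2")))
  labs <- classify_clonality(presence_matrix("P11", pres))
  expect_equal(as.character(labs), c("truncal", "private"),
               ignore_attr = TRUE)
  expect_equal(attr(labs, "counts")[["branch"]], 0L)

  # a patient with no truncal variants has truncal fraction exactly 0
  pres <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2,
                 dimnames = list(c("v1", "v2"), c("B1", "B2")))
  expect_equal(clonality_proportions(
    classify_clonality(presence_matrix("P01", pres)))[["truncal"]], 0)

  expect_warning(p <- clonality_proportions(factor(character())),
                 "undefined")
  expect_true(all(is.na(p)))
})

test_that("classification agrees with brute-force counting and is a partition", {
  set.seed(11)
  for (rep in 1:25) {
    pm <- random_presence_matrix(sample(2:6, 1), sample(5:40, 1))
    labs <- classify_clonality(pm)
    b <- ncol(pm$presence)
    # brute force: count present columns per variant
    for (v in rownames(pm$presence)) {
      m <- sum(pm$presence[v, ])
      expected <- if (m == b) "truncal" else if (m == 1) "private" else "branch"
      expect_identical(as.character(labs[[v]]), expected)
    }
    expect_equal(sum(attr(labs, "counts")), nrow(pm$presence))
    # monotonicity: dropping a column keeps or grows the truncal set
    if (b > 2) {
      drop <- sample.int(b, 1)
      sub <- pm$presence[, -drop, drop = FALSE]
      keep <- rowSums(sub) >= 1
      sub_pm <- presence_matrix(pm$patient_id, sub[keep, , drop = FALSE])
      sub_labs <- classify_clonality(sub_pm)
      was_truncal <- names(labs)[labs == "truncal"]
      expect_true(all(sub_labs[was_truncal] == "truncal"))
    }
  }
})

test_that("mutational load and pairwise diversity", {
  ml <- mutational_load(f1_matrix())
  expect_equal(unname(ml$per_biopsy), c(3L, 2L, 2L, 1L))
  expect_equal(ml$mean, 2)
  # pairwise |diffs| {1,1,2,0,1,1} -> mean 1
  expect_equal(ml$diversity_mean, 1)
  expect_equal(ml$sd, sd(c(3, 2, 2, 1)))

  pres <- matrix(TRUE, 5, 4, dimnames = list(paste0("v", 1:5),
                                             paste0("B", 1:4)))
  ml <- mutational_load(presence_matrix("C", pres))
  expect_equal(ml$diversity_mean, 0)
  expect_equal(ml$diversity_sd, 0)
})

test_that("panel filtering is a pure row filter", {
  pm <- f1_matrix()  # genes EGFR, TP53, TTN
  panel <- panel_definition("two", c("EGFR", "TP53"))
  out <- filter_panel(pm, panel)
  expect_equal(rownames(out$presence), c("v1", "v2"))
  expect_false(attr(out, "empty"))
  expect_true(all(rowSums(out$presence) >= 1))

  # identity when the panel covers everything
  all_panel <- panel_definition("all", pm$genes)
  expect_equal(filter_panel(pm, all_panel)$presence, pm$presence)

  # disjoint panel: legal empty result, flagged not fatal
  none <- filter_panel(pm, panel_definition("none", "BRAF"))
  expect_equal(nrow(none$presence), 0)
  expect_true(attr(none, "empty"))
})

test_that("driver annotation reports clonality and truncal fraction", {
  pm <- f1_matrix()
  labs <- classify_clonality(pm)
  res <- annotate_drivers(pm, labs, c("EGFR"))
  expect_equal(res$report$clonality, "truncal")
  expect_equal(res$fraction_truncal, 1)
  res <- annotate_drivers(pm, labs, c("TTN"))   # private driver
  expect_equal(res$fraction_truncal, 0)
  res <- annotate_drivers(pm, labs, c("BRAF"))  # absent driver
  expect_equal(nrow(res$report), 0)
  expect_true(is.na(res$fraction_truncal))
})

test_that("binary CNA events pass through the identical classifier", {
  # amplification/deletion segments encoded as event rows
  pres <- matrix(c(TRUE, TRUE, TRUE,    # amp chr8 in all -> truncal
                   TRUE, TRUE, FALSE,   # del chr17 shared -> branch
                   FALSE, FALSE, TRUE), 3, 3, byrow = TRUE,
                 dimnames = list(c("amp:8:q24", "del:17:p13", "amp:1:q21"),
                                 paste0("B", 1:3)))
  labs <- classify_clonality(presence_matrix("CNA", pres))
  expect_equal(as.character(labs), c("truncal", "branch", "private"),
               ignore_attr = TRUE)
})
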