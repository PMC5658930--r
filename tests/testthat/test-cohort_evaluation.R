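test_that("arm filters tabulate the bundled cohort into the published rows", {
  cohort <- load_cohort("charite2012")
  tabs <- published_tables()
  for (key in c("charite_total", "charite_single_agent",
                "charite_combination")) {
    arm <- sub("charite_", "", key)
    if (arm == "total") arm <- "all"
    got <- tabulate_cohort(cohort, arm = arm)
    expect_equal(as.character(got$class), c("SR", "MR", "ER"))
    expect_equal(got$responders, tabs[[key]]$r, info = key)
    expect_equal(got$n, tabs[[key]]$n, info = key)
  }
  expect_error(tabulate_cohort(cohort[0, ], "all"),
               class = "ctr_empty_cohort_error")
})

test_that("Clopper-Pearson matches binom.test on a grid", {
  for (n in c(1, 3, 7, 12, 28)) {
    for (x in unique(c(0, 1, floor(n / 2), n))) {
      got <- clopper_pearson(x, n)
      ref <- binom.test(x, n)$conf.int
      expect_equal(got$lower, ref[1], tolerance = 1e-12)
      expect_equal(got$upper, ref[2], tolerance = 1e-12)
      expect_equal(got$point, x / n)
    }
  }
  # closed form for x = 0: upper = 1 - (alpha/2)^(1/n)
  expect_equal(clopper_pearson(0, 4)$upper, 1 - 0.025^(1 / 4))
  expect_equal(round(clopper_pearson(0, 4)$upper, 3), 0.602)
  # boundary conventions
  expect_equal(clopper_pearson(0, 7)$lower, 0)
  expect_equal(clopper_pearson(7, 7)$upper, 1)
  expect_error(clopper_pearson(3, 0),
               class = "ctr_undefined_proportion_error")
  expect_error(clopper_pearson(5, 3), class = "ctr_consistency_error")
})

test_that("counts-based AUC equals the brute-force pairwise oracle", {
  for (key in names(published_tables())) {
    tab <- make_tab(key)
    expect_equal(ordinal_auc(tab), brute_force_auc(tab), info = key)
  }
  set.seed(42)
  for (i in 1:1000) {
    tab <- random_contingency()
    expect_equal(ordinal_auc(tab), brute_force_auc(tab))
  }
})

test_that("AUC and DeLong CI agree with pROC on the published tables", {
  library(pROC)
  for (key in names(published_tables())) {
    tab <- make_tab(key)
    d <- expand_contingency(tab)
    r <- pROC::roc(d$response, d$score, quiet = TRUE, direction = "<")
    expect_equal(ordinal_auc(tab), as.numeric(pROC::auc(r)), info = key)
    got <- delong_ci(tab)
    ref <- as.numeric(pROC::ci.auc(r, method = "delong"))
    expect_equal(got$ci_lower, max(0, ref[1]), tolerance = 1e-10, info = key)
    expect_equal(got$ci_upper, min(1, ref[3]), tolerance = 1e-10, info = key)
    expect_equal(got$variance, as.numeric(pROC::var(r, method = "delong")),
                 tolerance = 1e-10, info = key)
  }
})

test_that("AUC limiting cases behave as expected", {
  # perfect separation
  sep <- ordinal_contingency(c(10, 0, 0), c(10, 0, 8), c("SR", "MR", "ER"))
  expect_equal(ordinal_auc(sep), 1.0)
  d <- delong_ci(sep)
  expect_equal(d$variance, 0)
  expect_equal(c(d$ci_lower, d$ci_upper), c(1, 1))
  expect_true(any(roc_points(sep)$fpr == 0 & roc_points(sep)$tpr == 1))
  # identical class distributions in both groups
  null <- ordinal_contingency(c(10, 6, 4), c(20, 12, 8), c("SR", "MR", "ER"))
  expect_equal(ordinal_auc(null), 0.5)
  # one class only
  one <- ordinal_contingency(c(0, 5, 0), c(0, 9, 0), c("SR", "MR", "ER"))
  expect_equal(ordinal_auc(one), 0.5)
  pts <- roc_points(one)
  expect_equal(trapezoid_area(pts), 0.5)
  # degenerate groups
  empty <- ordinal_contingency(c(3, 2, 1), c(3, 2, 1), c("SR", "MR", "ER"))
  expect_error(ordinal_auc(empty), class = "ctr_degenerate_roc_error")
  tiny <- ordinal_contingency(c(1, 0, 0), c(1, 0, 3), c("SR", "MR", "ER"))
  expect_error(delong_ci(tiny), class = "ctr_variance_undefined_error")
})

test_that("relabelling the response groups maps auc to 1 - auc", {
  set.seed(7)
  for (i in 1:200) {
    tab <- random_contingency()
    flipped <- ordinal_contingency(tab$n - tab$responders, tab$n,
                                   as.character(tab$class))
    expect_equal(ordinal_auc(flipped), 1 - ordinal_auc(tab))
  }
})

test_that("ROC points are monotone and their trapezoid area equals the AUC", {
  set.seed(99)
  tabs <- c(lapply(names(published_tables()), make_tab),
            replicate(200, random_contingency(), simplify = FALSE))
  for (tab in tabs) {
    pts <- roc_points(tab)
    expect_equal(pts$fpr[1], 0)
    expect_equal(pts$tpr[1], 0)
    expect_equal(pts$fpr[nrow(pts)], 1)
    expect_equal(pts$tpr[nrow(pts)], 1)
    expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
    expect_equal(trapezoid_area(pts), ordinal_auc(tab))
  }
})

test_that("percent rounding is half-up", {
  expect_equal(percent_round(c(0.645, 0.004, 0.996, 0.5)), c(65, 0, 100, 50))
  expect_equal(percent_round(22 / 28), 79)
  expect_equal(percent_round(9 / 79), 11)
})

test_that("five-level score contingency is a valid ordinal predictor", {
  cohort <- load_cohort("charite2012")
  tab5 <- tabulate_scores(cohort)
  expect_equal(sum(tab5$n), 33L)
  expect_equal(trapezoid_area(roc_points(tab5)), ordinal_auc(tab5))
  expect_equal(ordinal_auc(tab5), brute_force_auc(tab5))
  # collapsing scores {3,4} -> SR, {1,2} -> MR, {0} -> ER gives the 3-level AUC
  expect_false(isTRUE(all.equal(ordinal_auc(tab5),
                                ordinal_auc(tabulate_cohort(cohort,
                                                            "combination")))))
})

test_that("evaluation bundles accuracy table and AUC consistently", {
  ev <- evaluate_cohort(load_cohort("charite2012"), arm = "combination",
                        label = "combination")
  expect_s3_class(ev, "ctr_evaluation")
  expect_equal(ev$accuracy$class, c("SR", "MR", "ER"))
  expect_equal(ev$accuracy$percent, c(95, 64, 0))
  expect_equal(ev$auc$auc, 0.85)
  expect_output(print(ev), "AUC")
})
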