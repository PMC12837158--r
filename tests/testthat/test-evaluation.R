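test_that("confusion metrics reproduce the worked diagnostic table", {
  cm <- confusion_metrics(confusion_counts(tp = 5, fp = 3, tn = 7, fn = 0))
  g <- function(metric) cm[cm$metric == metric, ]
  expect_equal(g("sensitivity")$estimate, 100)
  expect_equal(g("specificity")$estimate, 70)
  expect_equal(g("ppv")$estimate, 62.5)
  expect_equal(g("npv")$estimate, 100)
  expect_equal(g("accuracy")$estimate, 80)
  expect_equal(g("lr_positive")$estimate, 10 / 3, tolerance = 1e-9)
  expect_equal(g("lr_negative")$estimate, 0)
  expect_equal(g("auc")$estimate, 0.85)

  expect_equal(round(c(g("sensitivity")$lower, g("sensitivity")$upper), 1),
               c(47.8, 100))
  expect_equal(round(c(g("specificity")$lower, g("specificity")$upper), 1),
               c(34.8, 93.3))
  expect_equal(round(c(g("ppv")$lower, g("ppv")$upper), 1), c(39.3, 81.1))
  expect_equal(round(c(g("npv")$lower, g("npv")$upper), 1), c(59.0, 100))
  expect_equal(round(c(g("accuracy")$lower, g("accuracy")$upper), 1),
               c(51.9, 95.7))
  expect_equal(round(c(g("lr_positive")$lower, g("lr_positive")$upper), 2),
               c(1.29, 8.59))
  expect_equal(g("lr_negative")$lower, 0)

  perfect <- confusion_metrics(confusion_counts(1, 0, 1, 0))
  expect_true(all(perfect$estimate[perfect$metric %in%
    c("sensitivity", "specificity", "ppv", "npv", "accuracy")] == 100))
  expect_error(confusion_counts(-1, 0, 1, 0), "non-negative")
})

test_that("binary AUC equals exhaustive pair counting", {
  expect_equal(binary_auc(confusion_counts(5, 3, 7, 0)), 0.85)
  expect_equal(binary_auc(confusion_counts(4, 0, 6, 0)), 1)
  expect_equal(binary_auc(confusion_counts(3, 4, 4, 3)), 0.5)
  set.seed(8)
  for (i in 1:12) {
    cts <- as.list(rpois(4, 4) + c(1, 0, 1, 0))
    names(cts) <- c("tp", "fp", "tn", "fn")
    cc <- do.call(confusion_counts, cts)
    expect_equal(binary_auc(cc),
                 auc_bruteforce(cts$tp, cts$fp, cts$tn, cts$fn))
  }
  expect_error(binary_auc(confusion_counts(0, 3, 7, 0)), "both classes")
})

test_that("group comparison handles identical, separated and sampled data", {
  same <- compare_eri_groups(c(0.4, 0.4, 0.4), c(0.4, 0.4, 0.4))
  expect_equal(same$t_p, 1)

  sep <- compare_eri_groups(c(1, 1, 1), c(0, 0, 0))
  expect_lt(sep$u_p, 0.05)

  # two groups at the reported index moments: detectable at alpha = 0.05
  set.seed(1)
  pos <- rnorm(5, 0.85, 0.10)
  neg <- rnorm(10, 0.39, 0.11)
  res <- compare_eri_groups(pos, neg)
  expect_lt(res$t_p, 0.05)
  expect_gt(res$mean_pos, res$mean_neg)

  expect_error(compare_eri_groups(0.5, c(0.1, 0.2)), "n >= 2")
})

test_that("standardized mean differences follow their definitions", {
  expect_equal(smd(c(0, 1, 2), c(0, 1, 2)), 0)
  set.seed(5)
  a <- rnorm(2000, 1, 1)
  b <- rnorm(2000, 0, 1)
  expect_equal(smd(a, b), 1, tolerance = 0.1)
  expect_equal(smd(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)  # binary 0.5 vs 0.5
  expect_warning(s <- smd(c(1, 1), c(0, 0), type = "continuous"),
                 "infinite")
  expect_true(is.infinite(s))
})

test_that("caliper matching picks the in-caliper control and never reuses", {
  # one treated, one control inside the caliper, one far outside
  cohort <- data.frame(x = c(0, 0.05, 3), group = c(1, 0, 0))
  ps <- c(0.5, 0.52, 0.95)
  mr <- propensity_match(cohort, "x", ratio = 1, propensity = ps)
  expect_equal(unname(unlist(mr$control_ids)), 2L)

  co <- generate_cohort(400, confounding = 0.5, seed = 9)
  covs <- c("age", "male", "bmi", "smoking", "hostile_neck", "neck_angle")
  mr2 <- suppressWarnings(propensity_match(co, covs))
  ctl <- unlist(mr2$control_ids)
  expect_equal(anyDuplicated(ctl), 0L)
  expect_true(all(co$group[ctl] == 0))
  expect_true(all(lengths(mr2$control_ids) == 3L))
  # every match within the caliper on logit propensity
  lps <- qlogis(mr2$propensity)
  for (t in names(mr2$control_ids))
    expect_true(all(abs(lps[mr2$control_ids[[t]]] -
                          lps[as.integer(t)]) <= mr2$caliper + 1e-12))
})

test_that("matching a confounded cohort improves covariate balance", {
  co <- generate_cohort(800, confounding = 1, seed = 13)
  covs <- c("age", "male", "bmi", "htn", "dm", "cad", "copd", "ckd",
            "smoking", "hostile_neck", "neck_angle", "neck_length",
            "neck_diameter")
  mr <- suppressWarnings(propensity_match(co, covs))
  expect_lt(max(abs(mr$smd_post)), max(abs(mr$smd_pre)))
  expect_error(propensity_match(co[co$group == 1, ], covs), "both groups")
})
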