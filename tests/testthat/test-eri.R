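test_that("the index follows its composite formula and cutoff rule", {
  z <- compute_eri(list(ac = 0, sgs2 = 0, sgm2 = 0))
  expect_equal(z$eri, 0)
  expect_equal(z$prediction, "negative")

  m <- compute_eri(list(ac = 1, sgs2 = 1, sgm2 = 1))
  expect_equal(m$raw, 2.5)
  expect_equal(m$eri, 1)
  expect_equal(m$prediction, "positive")

  h <- compute_eri(list(ac = 0.5, sgs2 = 0.5, sgm2 = 0.5))
  expect_equal(h$raw, 1.25)
  expect_equal(h$eri, 0.5)

  expect_error(compute_eri(list(ac = 1.2, sgs2 = 0, sgm2 = 0)), "\\[0, 1\\]")
})

test_that("classification is boundary-inclusive on the positive side", {
  expect_equal(classify(0.85), "positive")
  expect_equal(classify(0.39), "negative")
  expect_equal(classify(0.80), "positive")
  expect_equal(classify(0.80 - 1e-9), "negative")
  expect_error(classify(0.5, cutoff = 1.2), "cutoff")
})

test_that("the index is monotone non-decreasing in each feature", {
  base <- c(ac = 0.2, sgs2 = 0.3, sgm2 = 0.4)
  for (feat in names(base)) {
    vals <- vapply(seq(0, 1, by = 0.1), function(v) {
      f <- as.list(base)
      f[[feat]] <- v
      compute_eri(f)$eri
    }, 1)
    expect_true(all(diff(vals) >= 0))
  }
})

test_that("risk model separates the declared generating rule", {
  co <- generate_cohort(500, seed = 7)
  tr <- co[1:350, ]
  te <- co[351:500, ]
  m <- fit_risk_model(tr[, c("ac", "sgs2", "sgm2")], tr$label, seed = 7)
  p <- predict(m, te)
  expect_true(all(p > 0 & p < 1))
  expect_gte(select_cutoff_roc(p, te$label)$auc, 0.9)

  # declared weight ordering: malapposition dominant, conicity second,
  # shape score near zero
  cf <- coef(m)
  expect_gt(cf[["sgm2"]], cf[["ac"]] * 0)
  expect_gt(cf[["sgm2"]], 0)
  expect_gt(cf[["ac"]], 0)
  expect_gt(cf[["sgm2"]], abs(cf[["sgs2"]]))
  expect_gt(cf[["ac"]], abs(cf[["sgs2"]]))

  # permuted labels: chance-level held-out AUC
  set.seed(99)
  expect_lt(abs(select_cutoff_roc(p, sample(te$label))$auc - 0.5), 0.1)

  expect_error(fit_risk_model(tr[, c("ac", "sgs2", "sgm2")],
                              rep(1, nrow(tr))), "both")
  expect_error(fit_risk_model(tr[1:10, c("ac", "sgs2", "sgm2")],
                              tr$label[1:10]), "n >= 20")
})

test_that("separable data get a finite ridge-penalized fit", {
  set.seed(4)
  f <- data.frame(ac = c(runif(30, 0, 0.2), runif(30, 0.6, 1)),
                  sgs2 = runif(60), sgm2 = runif(60))
  y <- rep(0:1, each = 30)
  m <- fit_risk_model(f, y)
  expect_true(all(is.finite(coef(m))))
  expect_true(m$penalized)
  expect_equal(predict(m, f, type = "class"), y)
})

test_that("ROC cutoff selection matches exhaustive pair counting", {
  r <- select_cutoff_roc(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_true(r$cutoff > 0.1 && r$cutoff <= 0.9)

  expect_warning(r2 <- select_cutoff_roc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)),
                 "constant")
  expect_equal(r2$auc, 0.5)

  # AUC = 0.75 by brute force over all positive/negative pairs
  sc <- c(0.9, 0.6, 0.4, 0.1)
  y <- c(1, 0, 1, 0)
  pairs <- expand.grid(p = sc[y == 1], n = sc[y == 0])
  bf <- mean(ifelse(pairs$p > pairs$n, 1, ifelse(pairs$p == pairs$n, 0.5, 0)))
  expect_equal(select_cutoff_roc(sc, y)$auc, bf)
  expect_equal(bf, 0.75)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  sc <- round(runif(60), 2)   # force ties
  y <- rbinom(60, 1, plogis(3 * sc - 1.5))
  if (length(unique(y)) < 2) y[1:2] <- 0:1
  ours <- select_cutoff_roc(sc, y)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})
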