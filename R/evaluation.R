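#' Confusion counts
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  if (sum(v) == 0) stop("empty confusion table")
  structure(as.list(v), class = "confusion_counts")
}

#' Tabulate confusion counts from predictions and labels
#'
#' @param predicted binary predictions (1/`"positive"` = event).
#' @param actual binary labels (1 = event).
#' @return a [confusion_counts()].
#' @export
tabulate_confusion <- function(predicted, actual) {
  p <- if (is.character(predicted) || is.factor(predicted))
    as.integer(as.character(predicted) == "positive") else as.integer(predicted)
  a <- as.integer(actual)
  confusion_counts(tp = sum(p == 1 & a == 1), fp = sum(p == 1 & a == 0),
                   tn = sum(p == 0 & a == 0), fn = sum(p == 0 & a == 1))
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts: TP %d, FP %d, TN %d, FN %d (n = %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

# Exact Clopper-Pearson interval for x successes in n trials, as percent.
.cp_interval <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  ci <- stats::binom.test(x, n, conf.level = conf)$conf.int
  100 * as.numeric(ci)
}

# Log-method CI for a likelihood ratio from confusion counts.
.lr_interval <- function(num_x, num_n, den_x, den_n, lr, conf = 0.95) {
  if (num_x == 0 || den_x == 0) return(c(NA_real_, NA_real_))
  se <- sqrt(1 / num_x - 1 / num_n + 1 / den_x - 1 / den_n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  exp(log(lr) + c(-1, 1) * z * se)
}

#' Diagnostic-accuracy report from confusion counts
#'
#' Point estimates and 95% intervals of the standard test metrics:
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, predictive values,
#' accuracy, likelihood ratios `LR+ = sens/(1-spec)` / `LR- = (1-sens)/spec`,
#' and the binary-prediction AUC `(sens + spec)/2`. Proportion intervals are
#' exact Clopper-Pearson; likelihood-ratio intervals use the standard log
#' method. The PPV interval is obtained by propagating the LR+ interval
#' through the sample prevalence (the convention of the common
#' diagnostic-test calculators); when the corresponding likelihood ratio is
#' degenerate (zero or undefined, e.g. LR- = 0 when FN = 0), the predictive
#' value falls back to its exact binomial interval. The AUC interval is
#' Hanley-McNeil. Metrics with a zero denominator are reported as `NA`.
#'
#' @param counts a [confusion_counts()].
#' @param conf confidence level.
#' @return An object of class `diagnostic_report`: a data.frame with one row
#'   per metric (`estimate`, `lower`, `upper`; proportions in percent) plus
#'   the counts as an attribute.
#' @export
confusion_metrics <- function(counts, conf = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  npos <- tp + fn
  nneg <- tn + fp
  sens <- if (npos > 0) tp / npos else NA_real_
  spec <- if (nneg > 0) tn / nneg else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  acc <- (tp + tn) / n
  prev <- npos / n
  lr_pos <- if (!is.na(sens) && !is.na(spec) && spec < 1)
    sens / (1 - spec) else if (isTRUE(spec == 1)) NA_real_ else NA_real_
  lr_neg <- if (!is.na(sens) && !is.na(spec) && spec > 0)
    (1 - sens) / spec else NA_real_
  lrp_ci <- if (!is.na(lr_pos))
    .lr_interval(tp, npos, fp, nneg, lr_pos, conf) else c(NA, NA)
  lrn_ci <- if (!is.na(lr_neg) && lr_neg > 0)
    .lr_interval(fn, npos, tn, nneg, lr_neg, conf) else c(NA, NA)
  if (!is.na(lr_neg) && lr_neg == 0) lrn_ci <- c(0, NA)

  # predictive-value intervals: LR propagation through prevalence where the
  # LR interval exists, exact binomial on the predictive count otherwise
  odds <- prev / (1 - prev)
  ppv_ci <- if (!anyNA(lrp_ci)) {
    100 * (lrp_ci * odds) / (lrp_ci * odds + 1)
  } else .cp_interval(tp, tp + fp, conf)
  npv_ci <- if (!anyNA(lrn_ci)) {
    100 / (1 + lrn_ci * odds)
  } else .cp_interval(tn, tn + fn, conf)
  npv_ci <- sort(npv_ci)

  auc <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
  auc_ci <- if (!is.na(auc)) .hanley_mcneil(auc, npos, nneg, conf) else c(NA, NA)

  tab <- data.frame(
    metric = c("sensitivity", "specificity", "ppv", "npv", "accuracy",
               "lr_positive", "lr_negative", "auc"),
    estimate = c(100 * sens, 100 * spec, 100 * ppv, 100 * npv, 100 * acc,
                 lr_pos, lr_neg, auc),
    lower = c(.cp_interval(tp, npos, conf)[1],
              .cp_interval(tn, nneg, conf)[1],
              ppv_ci[1], npv_ci[1],
              .cp_interval(tp + tn, n, conf)[1],
              lrp_ci[1], lrn_ci[1], auc_ci[1]),
    upper = c(.cp_interval(tp, npos, conf)[2],
              .cp_interval(tn, nneg, conf)[2],
              ppv_ci[2], npv_ci[2],
              .cp_interval(tp + tn, n, conf)[2],
              lrp_ci[2], lrn_ci[2], auc_ci[2]))
  structure(tab, counts = counts, conf = conf,
            class = c("diagnostic_report", "data.frame"))
}

.hanley_mcneil <- function(auc, n1, n0, conf = 0.95) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  pmin(pmax(auc + c(-1, 1) * z * se, 0), 1)
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cts <- attr(x, "counts")
  cat(sprintf("diagnostic_report (TP %d / FP %d / TN %d / FN %d):\n",
              cts$tp, cts$fp, cts$tn, cts$fn))
  fmt <- function(r) {
    pct <- r$metric %in% c("sensitivity", "specificity", "ppv", "npv",
                           "accuracy")
    sprintf("  %-12s %s (%s-%s)", r$metric,
            formatC(r$estimate, digits = if (pct) 1 else 2, format = "f"),
            formatC(r$lower, digits = if (pct) 1 else 2, format = "f"),
            formatC(r$upper, digits = if (pct) 1 else 2, format = "f"))
  }
  for (i in seq_len(nrow(x))) cat(fmt(x[i, ]), "\n")
  invisible(x)
}

#' Empirical AUC of a binary prediction
#'
#' With a dichotomous score the ROC has a single interior operating point and
#' the empirical AUC reduces to
#' `[TP*TN + 0.5*(TP*FP + FN*TN)] / [(TP+FN)*(TN+FP)] = (sens + spec) / 2`:
#' concordant positive/negative pairs count 1, tied pairs count one half.
#'
#' @param counts a [confusion_counts()] with both classes present.
#' @return AUC in \[0, 1\].
#' @export
binary_auc <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  npos <- counts$tp + counts$fn
  nneg <- counts$tn + counts$fp
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  (counts$tp * counts$tn +
     0.5 * (counts$tp * counts$fp + counts$fn * counts$tn)) / (npos * nneg)
}

#' Compare ERI distributions between outcome groups
#'
#' Welch two-sample two-tailed t-test of the index between endoleak-positive
#' and endoleak-negative cases, with a Mann-Whitney U test as a secondary
#' rank-based report for small-sample robustness.
#'
#' @param pos ERI values of the event group (n >= 2).
#' @param neg ERI values of the non-event group (n >= 2).
#' @return list with group means/SDs, `t_p` (Welch), `u_p` (Mann-Whitney),
#'   and the underlying test objects.
#' @export
compare_eri_groups <- function(pos, neg) {
  if (length(pos) < 2 || length(neg) < 2) stop("each group needs n >= 2")
  if (stats::sd(pos) == 0 && stats::sd(neg) == 0 &&
      mean(pos) == mean(neg)) {
    return(list(mean_pos = mean(pos), sd_pos = 0, mean_neg = mean(neg),
                sd_neg = 0, t_p = 1, u_p = 1, t_test = NULL, u_test = NULL))
  }
  tt <- tryCatch(stats::t.test(pos, neg), error = function(e) NULL)
  ut <- suppressWarnings(stats::wilcox.test(pos, neg, exact = FALSE))
  list(mean_pos = mean(pos), sd_pos = stats::sd(pos),
       mean_neg = mean(neg), sd_neg = stats::sd(neg),
       t_p = if (is.null(tt)) NA_real_ else tt$p.value,
       u_p = ut$p.value, t_test = tt, u_test = ut)
}

#' Standardized mean difference
#'
#' Continuous: `(m1 - m2) / sqrt((s1^2 + s2^2)/2)`. Binary:
#' `(p1 - p2) / sqrt((p1(1-p1) + p2(1-p2))/2)`. An infinite value (zero
#' pooled variance with unequal means) is returned as `Inf` with a warning.
#'
#' @param treated,control covariate values in the two arms.
#' @param type `"continuous"` or `"binary"` (auto-detected for 0/1 data).
#' @return signed SMD.
#' @export
smd <- function(treated, control, type = NULL) {
  if (is.null(type)) {
    type <- if (all(c(treated, control) %in% c(0, 1))) "binary"
    else "continuous"
  }
  if (type == "binary") {
    p1 <- mean(treated)
    p2 <- mean(control)
    s <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
  } else {
    if (length(treated) < 2 || length(control) < 2)
      stop("continuous SMD needs n >= 2 per arm")
    p1 <- mean(treated)
    p2 <- mean(control)
    s <- sqrt((stats::var(treated) + stats::var(control)) / 2)
  }
  if (s == 0) {
    if (p1 == p2) return(0)
    warning("zero pooled variance with unequal means: infinite SMD")
    return(Inf * sign(p1 - p2))
  }
  (p1 - p2) / s
}

#' Propensity-score matching with a logit caliper
#'
#' Estimates the propensity of belonging to the treated group by logistic
#' regression on the supplied covariates, then performs greedy 1:`ratio`
#' nearest-neighbour matching without replacement on the logit of the
#' propensity score, processing treated units in descending propensity
#' order. Matches beyond the caliper — `caliper_sd` standard deviations of
#' the logit propensity score — are forbidden; treated units that cannot be
#' given `ratio` in-caliper controls keep their partial match set and are
#' counted in `n_incomplete` (fully unmatched units in `n_unmatched`) with a
#' warning.
#'
#' @param cohort data.frame containing `group` (1 = treated) and the
#'   covariates.
#' @param covariates character vector of covariate column names.
#' @param ratio controls per treated unit.
#' @param caliper_sd caliper width in SDs of logit(PS).
#' @param propensity optional known propensity scores (one per row of
#'   `cohort`), bypassing the logistic model.
#' @return An object of class `match_result`: `treated_ids`, `control_ids`
#'   (list per treated unit), `propensity`, `caliper`, pre/post SMD tables
#'   and the matched cohort row indices.
#' @export
propensity_match <- function(cohort, covariates, ratio = 3,
                             caliper_sd = 0.2, propensity = NULL) {
  if (!"group" %in% names(cohort)) stop("cohort needs a 'group' column")
  if (!all(covariates %in% names(cohort)))
    stop("missing covariate columns: ",
         paste(setdiff(covariates, names(cohort)), collapse = ", "))
  if (anyNA(cohort[, covariates])) stop("covariates must be complete")
  g <- as.integer(cohort$group)
  if (length(unique(g)) < 2) stop("both groups must be present")
  if (is.null(propensity)) {
    fml <- stats::as.formula(paste("g ~",
                                   paste(covariates, collapse = " + ")))
    dat <- cbind(g = g, cohort[, covariates, drop = FALSE])
    ps_fit <- stats::glm(fml, data = dat, family = stats::binomial())
    ps <- stats::fitted(ps_fit)
  } else {
    if (length(propensity) != nrow(cohort))
      stop("propensity must have one score per cohort row")
    ps <- propensity
  }
  lps <- stats::qlogis(pmin(pmax(ps, 1e-12), 1 - 1e-12))
  caliper <- caliper_sd * stats::sd(lps)
  treated <- which(g == 1)
  controls <- which(g == 0)
  avail <- rep(TRUE, length(lps))
  order_t <- treated[order(ps[treated], decreasing = TRUE)]
  matches <- vector("list", length(order_t))
  names(matches) <- as.character(order_t)
  for (ti in order_t) {
    d <- abs(lps[controls] - lps[ti])
    ok <- which(avail[controls] & d <= caliper)
    if (length(ok) < ratio) next       # drop treated unit: too few in caliper
    sel <- controls[ok[order(d[ok])][seq_len(ratio)]]
    avail[sel] <- FALSE
    matches[[as.character(ti)]] <- sel
  }
  n_ctrl <- lengths(matches)
  n_unmatched <- sum(n_ctrl == 0)
  n_incomplete <- n_unmatched
  if (n_unmatched > 0)
    warning(sprintf("%d treated unit(s) dropped: fewer than %d controls within the caliper",
                    n_unmatched, ratio))
  matched_treated <- as.integer(names(matches))[n_ctrl > 0]
  matched_controls <- unlist(matches)
  smd_tab <- function(t_idx, c_idx) {
    vapply(covariates, function(cv)
      tryCatch(smd(cohort[[cv]][t_idx], cohort[[cv]][c_idx]),
               error = function(e) NA_real_), 1)
  }
  pre <- smd_tab(treated, controls)
  post <- smd_tab(matched_treated, matched_controls)
  structure(list(treated_ids = matched_treated,
                 control_ids = matches[n_ctrl > 0],
                 propensity = ps, caliper = caliper,
                 smd_pre = pre, smd_post = post,
                 n_unmatched = n_unmatched, n_incomplete = n_incomplete,
                 ratio = ratio),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: %d treated matched 1:%d (caliper %.3f on logit PS)\n",
              length(x$treated_ids), x$ratio, x$caliper))
  cat(sprintf("  unmatched treated: %d; max |SMD| pre %.3f -> post %.3f\n",
              x$n_unmatched, max(abs(x$smd_pre)), max(abs(x$smd_post))))
  invisible(x)
}

#' @export
summary.match_result <- function(object, ...) {
  print(object)
  cat("\ncovariate balance (SMD):\n")
  print(round(data.frame(pre = object$smd_pre, post = object$smd_post), 4))
  invisible(object)
}
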