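#' Endoleak Risk Index (ERI)
#'
#' Aggregates the three apposition features into the composite risk score
#' \deqn{ERI_{raw} = AC + SGS_2 + SGM_2 / 2} and normalizes it by its maximum
#' attainable value (2.5, since each feature lies in \[0, 1\]) to a
#' dimensionless index in \[0, 1\]. The binary prediction is positive when
#' the normalized index reaches the decision cutoff, 0.80 by default; an
#' index below the cutoff supports proceeding with a standard device.
#'
#' @param features a [risk_features()] object, or a named list/vector with
#'   elements `ac`, `sgs2`, `sgm2`, each in \[0, 1\].
#' @param cutoff decision threshold on the normalized index, in (0, 1).
#' @return An object of class `eri_result`: `raw`, `eri` (normalized),
#'   `cutoff`, `prediction` (`"positive"`/`"negative"`), and the feature
#'   breakdown.
#' @examples
#' compute_eri(list(ac = 0.5, sgs2 = 0.5, sgm2 = 0.5))
#' @export
compute_eri <- function(features, cutoff = 0.80) {
  f <- c(ac = features$ac, sgs2 = features$sgs2, sgm2 = features$sgm2)
  if (anyNA(f)) stop("features must provide ac, sgs2 and sgm2")
  if (any(f < 0 | f > 1)) stop("features must lie in [0, 1]")
  raw <- f[["ac"]] + f[["sgs2"]] + f[["sgm2"]] / 2
  eri <- raw / 2.5
  structure(list(raw = raw, eri = eri, cutoff = cutoff,
                 prediction = classify(eri, cutoff),
                 features = as.list(f)),
            class = "eri_result")
}

#' Binary endoleak prediction from an index value
#'
#' Positive iff the index is at or above the cutoff (the boundary counts as
#' positive: only an index strictly below the threshold rules the risk out).
#'
#' @param eri an `eri_result` or a numeric index in \[0, 1\].
#' @param cutoff decision threshold in (0, 1).
#' @return `"positive"` or `"negative"` (vectorized over numeric input).
#' @export
classify <- function(eri, cutoff = 0.80) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  val <- if (inherits(eri, "eri_result")) eri$eri else eri
  ifelse(val >= cutoff, "positive", "negative")
}

#' @export
print.eri_result <- function(x, ...) {
  cat(sprintf("ERI = %.4f (raw %.4f / 2.5), cutoff %.2f -> %s\n",
              x$eri, x$raw, x$cutoff, x$prediction))
  cat(sprintf("  AC = %.4f, SGS2 = %.4f, SGM2 = %.4f\n",
              x$features$ac, x$features$sgs2, x$features$sgm2))
  invisible(x)
}

#' Fit the logistic endoleak risk model
#'
#' Maximum-likelihood logistic regression of the binary endoleak label on the
#' three apposition features, the supervised layer trained on simulated
#' cohorts. When the data are separable (or the fit otherwise fails to
#' converge), a small ridge penalty on the slopes is applied via penalized
#' iteratively reweighted least squares to keep the coefficients finite.
#'
#' @param features data.frame with columns `ac`, `sgs2`, `sgm2`.
#' @param labels binary vector (0/1) of the same length.
#' @param seed integer recorded in the training descriptor.
#' @param ridge penalty used for the separable-data fallback.
#' @return An object of class `eri_risk_model` with `coefficients`
#'   (intercept + three slopes), `training` descriptor, and flags
#'   `converged`, `penalized`.
#' @export
fit_risk_model <- function(features, labels, seed = NA_integer_,
                           ridge = 1e-3) {
  features <- as.data.frame(features)
  need <- c("ac", "sgs2", "sgm2")
  if (!all(need %in% names(features)))
    stop("features need columns ac, sgs2, sgm2")
  y <- as.integer(labels)
  if (length(y) != nrow(features)) stop("features and labels length mismatch")
  if (length(y) < 20) stop("risk-model fitting needs n >= 20")
  if (length(unique(y)) < 2) stop("both endoleak classes must be present")
  X <- as.matrix(features[, need])
  fit <- suppressWarnings(stats::glm(y ~ ac + sgs2 + sgm2,
                                     data = cbind(features[, need],
                                                  y = y),
                                     family = stats::binomial()))
  separable <- !fit$converged || any(abs(stats::coef(fit)) > 25)
  penalized <- FALSE
  if (separable) {
    coefs <- .ridge_logistic(cbind(1, X), y, lambda = ridge)
    penalized <- TRUE
  } else {
    coefs <- stats::coef(fit)
  }
  names(coefs) <- c("(Intercept)", need)
  structure(list(coefficients = coefs,
                 training = list(n = length(y), seed = seed,
                                 prevalence = mean(y)),
                 converged = TRUE, penalized = penalized),
            class = "eri_risk_model")
}

# Ridge-penalized logistic IRLS (intercept unpenalized).
.ridge_logistic <- function(X, y, lambda, maxit = 100, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1)))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(X * w, X) + pen
    beta_new <- solve(H, crossprod(X * w, z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  as.vector(beta)
}

#' @export
coef.eri_risk_model <- function(object, ...) object$coefficients

#' @export
print.eri_risk_model <- function(x, ...) {
  cat("eri_risk_model (logistic):\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  trained on n = %d (prevalence %.2f)%s\n",
              x$training$n, x$training$prevalence,
              if (x$penalized) ", ridge-penalized (separable data)" else ""))
  invisible(x)
}

#' @export
summary.eri_risk_model <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
predict.eri_risk_model <- function(object, newdata,
                                   type = c("response", "link", "class"),
                                   cutoff = 0.5, ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  X <- cbind(1, as.matrix(newdata[, c("ac", "sgs2", "sgm2")]))
  eta <- as.vector(X %*% object$coefficients)
  switch(type,
         link = eta,
         response = stats::plogis(eta),
         class = as.integer(stats::plogis(eta) >= cutoff))
}

#' ROC analysis and optimal-cutoff selection
#'
#' Sweeps all score thresholds ("positive iff score >= t"), computes the full
#' ROC curve and the empirical AUC (Mann-Whitney statistic, ties counted
#' half), and selects the optimal cutoff by Youden's J = sensitivity +
#' specificity - 1; J-ties are broken toward the higher specificity (the
#' higher threshold).
#'
#' @param scores numeric risk scores.
#' @param labels binary labels (1 = event).
#' @return An object of class `roc_analysis`: `cutoff`, `auc`, `youden`, and
#'   the `roc` data.frame (`threshold`, `sensitivity`, `specificity`).
#' @export
select_cutoff_roc <- function(scores, labels) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (length(unique(scores)) == 1) {
    warning("constant scores: degenerate ROC, AUC = 0.5")
    return(structure(list(cutoff = scores[1], auc = 0.5, youden = 0,
                          roc = data.frame(threshold = scores[1],
                                           sensitivity = 1,
                                           specificity = 0)),
                     class = "roc_analysis"))
  }
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  auc <- (sum(rank(scores)[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  su <- sort(unique(scores))
  thr <- c(su[1] - 1, (su[-1] + su[-length(su)]) / 2, su[length(su)],
           su[length(su)] + 1)
  sens <- vapply(thr, function(t) mean(scores[y == 1] >= t), 1)
  spec <- vapply(thr, function(t) mean(scores[y == 0] < t), 1)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]
  structure(list(cutoff = thr[best], auc = auc, youden = j[best],
                 roc = data.frame(threshold = thr, sensitivity = sens,
                                  specificity = spec)),
            class = "roc_analysis")
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat(sprintf("roc_analysis: AUC = %.3f, optimal cutoff = %.3f (J = %.3f)\n",
              x$auc, x$cutoff, x$youden))
  invisible(x)
}

#' @export
plot.roc_analysis <- function(x, ...) {
  o <- order(1 - x$roc$specificity, x$roc$sensitivity)
  plot(1 - x$roc$specificity[o], x$roc$sensitivity[o], type = "s",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
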