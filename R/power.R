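#' Cohen f-squared sample-size analysis for a GLM
#'
#' Solves the limiting noncentral chi-square power equation for a
#' `u`-coefficient model: find the noncentrality lambda at which a
#' chi-square test with `u` degrees of freedom and significance `alpha`
#' attains the target power, then convert effect size to sample size by
#' the Cohen convention N = lambda / f2 (floored). With u = 5,
#' f2 = 0.02 (a small effect), alpha = 0.05 and power 0.80 this yields
#' 641 required trial-level observations.
#'
#' @param u Numerator degrees of freedom (number of model coefficients).
#' @param f2 Cohen's f-squared effect size (small = 0.02).
#' @param alpha Significance level.
#' @param power Target power.
#' @return List of class `power_spec`: `u`, `f2`, `alpha`, `power`,
#'   `lambda`, `N` (= floor(lambda / f2)).
#' @seealso [achieved_power()], [dogs_needed()]
#' @export
required_sample_size <- function(u = 5, f2 = 0.02, alpha = 0.05,
                                 power = 0.80) {
  stopifnot(u >= 1, f2 > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  if (power <= alpha) stop("infeasible: target power must exceed alpha")
  crit <- stats::qchisq(1 - alpha, df = u)
  f <- function(l) {
    stats::pchisq(crit, df = u, ncp = l, lower.tail = FALSE) - power
  }
  lambda <- stats::uniroot(f, c(1e-6, 1e4), tol = 1e-10)$root
  structure(list(u = u, f2 = f2, alpha = alpha, power = power,
                 lambda = lambda, N = floor(lambda / f2)),
            class = "power_spec")
}

#' @export
print.power_spec <- function(x, ...) {
  cat(sprintf(
    "<power_spec: u = %g, f2 = %g, alpha = %g, power = %g -> lambda = %.4f, N = %d>\n",
    x$u, x$f2, x$alpha, x$power, x$lambda, x$N))
  invisible(x)
}

#' @rdname required_sample_size
#' @param N Total number of observations.
#' @return `achieved_power()` returns the power of the chi-square test at
#'   noncentrality f2 * N.
#' @export
achieved_power <- function(u, f2, N, alpha = 0.05) {
  stopifnot(u >= 1, f2 > 0, N > 0, alpha > 0, alpha < 1)
  crit <- stats::qchisq(1 - alpha, df = u)
  stats::pchisq(crit, df = u, ncp = f2 * N, lower.tail = FALSE)
}

#' @rdname required_sample_size
#' @param points_per_dog Observations contributed per dog (two conditions
#'   of ten trials each = 20).
#' @return `dogs_needed()` returns `ceiling(N / points_per_dog)`.
#' @export
dogs_needed <- function(N, points_per_dog = 20) {
  stopifnot(N > 0, points_per_dog > 0)
  as.integer(ceiling(N / points_per_dog))
}

#' Binary classification metrics
#'
#' Computes the metric set used for individual-feature placement
#' predictors: accuracy, support-weighted one-vs-rest precision, recall
#' and F score, the Matthews correlation coefficient, and a rank-based
#' AUC. A class with no predicted positives contributes precision 0; an
#' MCC whose denominator is 0 is reported as 0; tied scores earn 0.5 AUC
#' credit, so a constant score gives AUC 0.5.
#'
#' @param truth Binary true labels (logical or 0/1).
#' @param pred Binary predicted labels.
#' @param scores Optional numeric scores for AUC; defaults to `pred`.
#' @return List of class `metrics_report`: `accuracy`, `precision`,
#'   `recall`, `f1`, `mcc`, `auc`.
#' @export
classification_metrics <- function(truth, pred, scores = NULL) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(truth) != length(pred)) stop("length mismatch")
  if (anyNA(truth) || anyNA(pred) ||
      !all(c(truth, pred) %in% c(0L, 1L))) {
    stop("labels must be binary 0/1")
  }
  if (is.null(scores)) scores <- as.numeric(pred)
  if (length(scores) != length(truth)) stop("length mismatch")
  n <- length(truth)
  tp <- sum(truth == 1L & pred == 1L); fp <- sum(truth == 0L & pred == 1L)
  fn <- sum(truth == 1L & pred == 0L); tn <- sum(truth == 0L & pred == 0L)
  accuracy <- (tp + tn) / n

  # one-vs-rest per class, weighted by class support
  per_class <- function(cls) {
    tpc <- sum(truth == cls & pred == cls)
    ppc <- sum(pred == cls)  # predicted positives for this class
    apc <- sum(truth == cls) # actual positives
    prec <- if (ppc == 0L) 0 else tpc / ppc
    rec <- if (apc == 0L) 0 else tpc / apc
    f <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(prec = prec, rec = rec, f = f, w = apc / n)
  }
  cls <- lapply(c(0L, 1L), per_class)
  wsum <- function(k) sum(vapply(cls, function(x) x[[k]] * x[["w"]], numeric(1)))
  precision <- wsum("prec"); recall <- wsum("rec"); f1 <- wsum("f")

  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom

  npos <- sum(truth == 1L); nneg <- n - npos
  auc <- if (npos == 0L || nneg == 0L) {
    NA_real_
  } else {
    # Mann-Whitney rank statistic; midranks give ties 0.5 credit
    r <- rank(scores, ties.method = "average")
    (sum(r[truth == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 f1 = f1, mcc = mcc, auc = auc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f | precision %.3f | recall %.3f | F %.3f | MCC %.3f | AUC %s\n",
    x$accuracy, x$precision, x$recall, x$f1, x$mcc,
    ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}
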