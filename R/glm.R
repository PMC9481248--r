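#' Fit the binomial placement model
#'
#' Fits a logistic-link binomial GLM of placement outcome (1 = placed,
#' 0 = released) on trial-level engineered features, by iteratively
#' reweighted least squares with a convergence tolerance of 1e-8 and at
#' most 100 iterations. Trials are pooled across dogs (no dog-level random
#' effect) and zero-interaction trials are included as all-zero feature
#' rows. The condition covariate is treatment-coded with a configurable
#' reference level, so its exponentiated coefficient is the adjusted odds
#' ratio of the non-reference condition.
#'
#' @param data Feature table (see [build_feature_table()]) or any
#'   data.frame holding the response and covariates.
#' @param covariates Ordered covariate names; default the five pruned
#'   model covariates ([model_covariates()]).
#' @param response Name of the binary response column (default `placed`;
#'   logical or 0/1).
#' @param condition_ref Reference level for the `condition` factor
#'   (default `"ramp"`, so the reported term is the human condition).
#' @return Object of class `placement_glm`: the underlying `glm` fit plus
#'   the model specification and covariate means used for marginal-mean
#'   curves. Supports `print()`, `summary()`, `coef()`, `vcov()`,
#'   `predict()`, `residuals()`, `simulate()` and `plot()`.
#' @examples
#' set.seed(1)
#' d <- data.frame(placed = rbinom(200, 1, 0.75))
#' fit <- placement_glm(d, covariates = character(0))
#' coef(fit)  # intercept = log(3) at prevalence 0.75
#' @export
placement_glm <- function(data, covariates = model_covariates(),
                          response = "placed", condition_ref = "ramp") {
  stopifnot(is.data.frame(data), response %in% names(data))
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    stop("covariates not in table: ", paste(missing_cov, collapse = ", "))
  }
  df <- data[c(response, covariates)]
  df[[response]] <- as.integer(df[[response]])
  if (anyNA(df[[response]]) || !all(df[[response]] %in% c(0L, 1L))) {
    stop("response must be binary 0/1 without missing values")
  }
  if (length(unique(df[[response]])) < 2L) {
    stop("degenerate response: all outcomes identical")
  }
  if ("condition" %in% covariates) {
    df$condition <- stats::relevel(factor(df$condition), ref = condition_ref)
  }
  num_cov <- covariates[vapply(df[covariates], is.numeric, TRUE)]
  const <- num_cov[vapply(df[num_cov], function(v) stats::sd(v) == 0, TRUE)]
  if (length(const)) {
    stop("constant covariate(s): ", paste(const, collapse = ", "))
  }
  form <- stats::as.formula(paste(
    response, "~", if (length(covariates)) paste(covariates, collapse = " + ")
    else "1"))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(),
               data = df,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) {
    stop("IRLS did not converge in ", fit$iter, " iterations; ",
         "deviance trace ends at ", format(fit$deviance))
  }
  beta <- stats::coef(fit)
  if (sep_warn && any(abs(beta[-1L]) > 10)) {
    culprit <- names(beta[-1L])[which.max(abs(beta[-1L]))]
    stop("perfect separation detected; separating covariate: ", culprit)
  }
  means <- vapply(df[num_cov], mean, numeric(1))
  structure(
    list(fit = fit, covariates = covariates, response = response,
         condition_ref = condition_ref, covariate_means = means,
         n = nrow(df), call = match.call()),
    class = "placement_glm")
}

#' @export
coef.placement_glm <- function(object, ...) stats::coef(object$fit)

#' @export
vcov.placement_glm <- function(object, ...) stats::vcov(object$fit)

#' @export
predict.placement_glm <- function(object, newdata = NULL,
                                  type = c("response", "link"), ...) {
  type <- match.arg(type)
  stats::predict(object$fit, newdata = newdata, type = type, ...)
}

#' @export
residuals.placement_glm <- function(object, ...) stats::residuals(object$fit, ...)

#' @export
simulate.placement_glm <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$fit, nsim = nsim, seed = seed, ...)
}

#' @export
print.placement_glm <- function(x, ...) {
  cat(sprintf("<placement_glm: %d trials, deviance %.2f, %d IRLS iterations>\n",
              x$n, x$fit$deviance, x$fit$iter))
  print(round(stats::coef(x$fit), 4))
  invisible(x)
}

#' @export
summary.placement_glm <- function(object, ci_method = "wald", ...) {
  out <- list(n = object$n, deviance = object$fit$deviance,
              aic = object$fit$aic, iterations = object$fit$iter,
              odds_ratios = odds_ratios(object, ci_method = ci_method))
  class(out) <- "summary.placement_glm"
  out
}

#' @export
print.summary.placement_glm <- function(x, ...) {
  cat(sprintf("Binomial placement GLM on %d trials (deviance %.2f, AIC %.2f)\n",
              x$n, x$deviance, x$aic))
  cat("Adjusted odds ratios:\n")
  ors <- x$odds_ratios
  ors[-1L] <- lapply(ors[-1L], round, digits = 4)
  print(ors)
  invisible(x)
}

#' Adjusted odds ratios with confidence intervals
#'
#' Exponentiates the fitted coefficients into adjusted odds ratios — each
#' covariate's multiplicative effect on the odds of placement per unit
#' (per second, per kPa, per bite/s), controlling for the others. 95%
#' intervals come from the profile likelihood by default (often asymmetric
#' around the OR) or from the Wald normal approximation.
#'
#' @param object A [placement_glm()] fit.
#' @param ci_method `"profile"` (default) or `"wald"`.
#' @param level Confidence level (default 0.95).
#' @return data.frame with one row per term (intercept first): `or`,
#'   `ci_low`, `ci_high` (2.5% / 97.5% by default), `z`, `p_value`.
#' @export
odds_ratios <- function(object, ci_method = c("profile", "wald"),
                        level = 0.95) {
  stopifnot(inherits(object, "placement_glm"))
  ci_method <- match.arg(ci_method)
  fit <- object$fit
  if (!fit$converged) stop("fit did not converge")
  beta <- stats::coef(fit)
  sm <- stats::summary.glm(fit)$coefficients
  ci <- if (ci_method == "profile") {
    loadNamespace("MASS")  # registers confint.glm (profile likelihood)
    # profiling refits at pinned extreme coefficients, which can push
    # fitted probabilities to 0/1; those warnings are expected there
    suppressWarnings(suppressMessages(stats::confint(fit, level = level)))
  } else {
    zq <- stats::qnorm(1 - (1 - level) / 2)
    cbind(beta - zq * sm[, "Std. Error"], beta + zq * sm[, "Std. Error"])
  }
  if (is.null(dim(ci))) ci <- matrix(ci, nrow = 1)
  data.frame(
    term = names(beta),
    or = exp(beta),
    ci_low = exp(ci[, 1L]),
    ci_high = exp(ci[, 2L]),
    z = sm[, "z value"],
    p_value = sm[, "Pr(>|z|)"],
    row.names = NULL)
}

#' Estimated-marginal-mean likelihood curve for one covariate
#'
#' Predicted probability of placement over a grid of one numeric
#' covariate, with every other numeric covariate held at its sample mean
#' (all analyzable trials, zero-interaction rows included) and the
#' condition fixed at a given level. The 95% band is computed on the
#' linear-predictor scale from the coefficient covariance (delta method)
#' and mapped through the inverse logit, so it always lies in [0, 1].
#'
#' @param object A [placement_glm()] fit.
#' @param feature Numeric covariate to sweep.
#' @param grid Numeric grid; default `n_grid` points over the observed
#'   range of the feature.
#' @param condition Condition level for the curve (default the reference
#'   level); ignored when `condition` is not in the model.
#' @param n_grid Grid resolution when `grid` is NULL.
#' @param level Confidence level.
#' @return data.frame `x, p_hat, ci_low, ci_high` with attributes
#'   `feature` and `condition`.
#' @export
emm_curve <- function(object, feature, grid = NULL, condition = NULL,
                      n_grid = 100, level = 0.95) {
  stopifnot(inherits(object, "placement_glm"))
  has_condition <- "condition" %in% object$covariates
  if (!feature %in% object$covariates || feature == "condition") {
    stop("feature not a numeric covariate of the model: ", feature)
  }
  mf <- object$fit$model
  if (is.null(grid)) {
    rng <- range(mf[[feature]])
    grid <- seq(rng[1L], rng[2L], length.out = n_grid)
  }
  nd <- as.data.frame(as.list(object$covariate_means))
  nd <- nd[rep(1L, length(grid)), , drop = FALSE]
  nd[[feature]] <- grid
  if (has_condition) {
    lev <- levels(mf$condition)
    if (is.null(condition)) condition <- object$condition_ref
    if (!condition %in% lev) stop("unknown condition level: ", condition)
    nd$condition <- factor(condition, levels = lev)
  }
  pr <- stats::predict(object$fit, newdata = nd, type = "link", se.fit = TRUE)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  inv_logit <- function(eta) 1 / (1 + exp(-eta))
  out <- data.frame(
    x = grid,
    p_hat = inv_logit(pr$fit),
    ci_low = inv_logit(pr$fit - zq * pr$se.fit),
    ci_high = inv_logit(pr$fit + zq * pr$se.fit))
  attr(out, "feature") <- feature
  attr(out, "condition") <- if (has_condition) condition else NA_character_
  out
}

#' @export
#' @param x A `placement_glm` object.
#' @param feature Covariate to plot (default: average bite duration).
#' @param conditions Condition levels to overlay (default: all).
#' @param ... Passed to [graphics::plot()].
#' @rdname emm_curve
plot.placement_glm <- function(x, feature = "avg_duration_s",
                               conditions = NULL, ...) {
  has_condition <- "condition" %in% x$covariates
  if (is.null(conditions)) {
    conditions <- if (has_condition) levels(x$fit$model$condition) else NA
  }
  curves <- lapply(conditions, function(cl) {
    emm_curve(x, feature, condition = if (has_condition) cl else NULL)
  })
  xs <- curves[[1L]]$x
  graphics::plot(xs, curves[[1L]]$p_hat, type = "n", ylim = c(0, 1),
                 xlab = feature, ylab = "P(placed)", ...)
  cols <- c("#d1495b", "#00798c", "#edae49", "#66a182")
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    graphics::polygon(c(cv$x, rev(cv$x)), c(cv$ci_low, rev(cv$ci_high)),
                      col = grDevices::adjustcolor(cols[i], 0.2), border = NA)
    graphics::lines(cv$x, cv$p_hat, col = cols[i], lwd = 2)
  }
  if (has_condition) {
    graphics::legend("topright", legend = conditions, col = cols, lwd = 2,
                     bty = "n")
  }
  invisible(x)
}
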