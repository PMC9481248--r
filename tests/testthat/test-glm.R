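test_that("intercept-only fit recovers the log-odds of prevalence exactly", {
  d <- data.frame(placed = rep(c(1, 0), c(30, 10)))
  fit <- placement_glm(d, covariates = character(0))
  expect_equal(unname(coef(fit)), log(3), tolerance = 1e-8)
  expect_equal(mean(predict(fit)), 0.75, tolerance = 1e-10)
})

test_that("degenerate and separated inputs fail with informative errors", {
  allsame <- data.frame(placed = rep(1, 20), x = rnorm(20))
  expect_error(placement_glm(allsame, covariates = "x"), "identical")

  set.seed(2)
  sep <- data.frame(x = c(rnorm(30, -3), rnorm(30, 3)))
  sep$placed <- as.integer(sep$x > 0)
  expect_error(placement_glm(sep, covariates = "x"), "separation.*x")

  const <- data.frame(placed = rbinom(20, 1, 0.5), x = rep(2, 20))
  expect_error(placement_glm(const, covariates = "x"), "constant")
})

test_that("a 2x2 table reproduces the closed-form ad/bc odds ratio", {
  d <- data.frame(
    x = rep(c(1, 1, 0, 0), c(10, 20, 30, 40)),
    placed = rep(c(1, 0, 1, 0), c(10, 20, 30, 40)))
  fit <- placement_glm(d, covariates = "x")
  expect_equal(unname(coef(fit)["x"]), log(2 / 3), tolerance = 1e-7)
  ors <- odds_ratios(fit, ci_method = "profile")
  expect_equal(ors$or[ors$term == "x"], 2 / 3, tolerance = 1e-6)
  expect_true(all(ors$ci_low <= ors$or + 1e-9 & ors$or <= ors$ci_high + 1e-9))
})

test_that("a null covariate yields OR 1 with a CI containing 1", {
  # perfectly balanced design: the slope is exactly zero
  d <- data.frame(x = rep(c(0, 0, 1, 1), each = 25),
                  placed = rep(c(0, 1, 0, 1), each = 25))
  fit <- placement_glm(d, covariates = "x")
  ors <- odds_ratios(fit, ci_method = "wald")
  r <- ors[ors$term == "x", ]
  expect_equal(r$or, 1, tolerance = 1e-7)
  expect_true(r$ci_low < 1 && r$ci_high > 1)
})

test_that("profile and Wald intervals agree at large n with moderate effects", {
  set.seed(12)
  n <- 1e4
  x <- rnorm(n)
  p <- 1 / (1 + exp(-(0.2 + 0.5 * x)))
  d <- data.frame(x = x, placed = rbinom(n, 1, p))
  fit <- placement_glm(d, covariates = "x")
  prof <- odds_ratios(fit, ci_method = "profile")
  wald <- odds_ratios(fit, ci_method = "wald")
  expect_equal(prof$ci_low, wald$ci_low, tolerance = 0.005)
  expect_equal(prof$ci_high, wald$ci_high, tolerance = 0.005)
  # coefficient recovery within 3 standard errors
  se <- sqrt(diag(vcov(fit)))["x"]
  expect_lt(abs(coef(fit)["x"] - 0.5), 3 * se)
})

test_that("mean fitted probability equals sample prevalence (score identity)", {
  feat <- default_features()
  fit <- placement_glm(feat)
  expect_equal(mean(predict(fit)), mean(as.integer(feat$placed)),
               tolerance = 1e-8)
  expect_equal(nrow(odds_ratios(fit, ci_method = "wald")), 6L)
})

test_that("marginal-mean curves are bounded, monotone, and match emmeans", {
  set.seed(30)
  n <- 800
  d <- data.frame(x = rexp(n, 5),
                  condition = sample(c("ramp", "human"), n, replace = TRUE))
  eta <- 0.5 - 2 * d$x + 0.3 * (d$condition == "human")
  d$placed <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  fit <- placement_glm(d, covariates = c("x", "condition"))

  cv <- emm_curve(fit, "x", condition = "human")
  expect_true(all(cv$ci_low <= cv$p_hat & cv$p_hat <= cv$ci_high))
  expect_true(all(cv$ci_low >= 0 & cv$ci_high <= 1))
  # negative fitted slope: strictly decreasing likelihood
  expect_true(coef(fit)["x"] < 0)
  expect_true(all(diff(cv$p_hat) < 0))
  # extreme grid points push the curve to the 0/1 asymptotes
  lo <- emm_curve(fit, "x", grid = c(-100, 100))
  expect_equal(lo$p_hat[1], 1, tolerance = 1e-6)
  expect_equal(lo$p_hat[2], 0, tolerance = 1e-6)

  expect_error(emm_curve(fit, "nope"), "not a numeric covariate")
  expect_error(emm_curve(fit, "x", condition = "alien"), "unknown condition")

  # cross-check against emmeans at the covariate mean
  at_mean <- emm_curve(fit, "x", grid = mean(d$x), condition = "human")
  em <- emmeans::emmeans(fit$fit, ~condition, type = "response",
                         at = list(x = mean(d$x)))
  em_df <- as.data.frame(em)
  expect_equal(at_mean$p_hat,
               em_df$prob[em_df$condition == "human"], tolerance = 1e-6)
  expect_equal(at_mean$ci_low,
               em_df$asymp.LCL[em_df$condition == "human"], tolerance = 1e-6)
})

test_that("flat models give flat curves at prevalence", {
  d <- data.frame(x = rep(c(0, 0, 1, 1), each = 25),
                  placed = rep(c(0, 1, 0, 1), each = 25))
  fit <- placement_glm(d, covariates = "x")
  cv <- emm_curve(fit, "x")
  expect_equal(cv$p_hat, rep(0.5, nrow(cv)), tolerance = 1e-7)
})

test_that("model object methods delegate coherently", {
  feat <- default_features()
  fit <- placement_glm(feat)
  expect_s3_class(fit, "placement_glm")
  expect_length(coef(fit), 6L)
  expect_equal(dim(vcov(fit)), c(6L, 6L))
  expect_equal(length(residuals(fit)), nrow(feat))
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(nrow(feat), 2L))
  out <- capture.output(print(summary(fit, ci_method = "wald")))
  expect_true(any(grepl("odds ratios", out, ignore.case = TRUE)))
})
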