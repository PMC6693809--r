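test_that("fit_ols reproduces exact fits and closed forms", {
  # exact line: y = 2x + 1 on 5 points
  x <- c(-2, -1, 0, 1, 2)
  X <- cbind(1, x)
  f <- fit_ols(X, 2 * x + 1)
  expect_equal(unname(f$estimate), c(1, 2), tolerance = 1e-12)
  expect_lt(f$residual_se, 1e-12)
  # intercept-only: mean and sd/sqrt(n)
  set.seed(4)
  y <- rnorm(25)
  f <- fit_ols(matrix(1, 25, 1), y)
  expect_equal(unname(f$estimate), mean(y), tolerance = 1e-12)
  expect_equal(unname(f$se), sd(y) / sqrt(25), tolerance = 1e-12)
  expect_equal(f$df, 24)
})

test_that("fit_ols matches hand-solved normal equations to 1e-10", {
  # points (0,1), (1,3), (2,4): slope Sxy/Sxx = 3/2, intercept 8/3 - 3/2
  f <- fit_ols(cbind(1, c(0, 1, 2)), c(1, 3, 4))
  expect_equal(unname(f$estimate), c(7 / 6, 3 / 2), tolerance = 1e-10)
  # a larger well-conditioned system against explicit solve(X'X, X'y)
  set.seed(7)
  X <- cbind(1, matrix(rnorm(300), 100, 3))
  y <- rnorm(100)
  expect_equal(unname(f2 <- fit_ols(X, y)$estimate),
               unname(drop(solve(crossprod(X), crossprod(X, y)))),
               tolerance = 1e-10)
})

test_that("fit_ols rejects rank deficiency and negative weights", {
  X <- cbind(1, c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_error(fit_ols(X, rnorm(4)), "rank-deficient")
  expect_error(fit_ols(cbind(1, 1:4), rnorm(4), weights = c(1, 1, -1, 1)),
               "negative weights")
})

test_that("weighted fit_ols matches lm and its sandwich variance", {
  skip_if_not_installed("sandwich")
  set.seed(11)
  n <- 80
  x <- rnorm(n); w <- runif(n, 0.5, 3)
  y <- 1 + 2 * x + rnorm(n)
  f <- fit_ols(cbind(`(Intercept)` = 1, x = x), y, weights = w)
  lmf <- lm(y ~ x, weights = w)
  expect_equal(unname(f$estimate), unname(coef(lmf)), tolerance = 1e-10)
  vs <- sandwich::vcovHC(lmf, type = "HC0")
  expect_equal(unname(f$se), unname(sqrt(diag(vs))), tolerance = 1e-8)
})

test_that("fit_logistic matches the 2x2 closed form and glm", {
  d <- records_2x2(20, 30, 40, 10)
  f <- fit_logistic(cbind(1, d$x), d$y)
  expect_equal(unname(f$estimate[2]), log(1 / 6), tolerance = 1e-8)
  expect_equal(unname(f$estimate[1]), log(4), tolerance = 1e-8)
  g <- glm(y ~ x, binomial, data = d)
  expect_equal(unname(f$estimate), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(g)))), tolerance = 1e-4)
})

test_that("fit_logistic: symmetry gives a null slope", {
  x <- rep(c(-1, 1), each = 20)
  y <- rep(c(0, 1), 20)   # y independent of x by construction
  f <- fit_logistic(cbind(1, x), y)
  expect_lt(abs(f$estimate[2]), 1e-8)
})

test_that("fit_logistic log-likelihood is non-decreasing over IRLS", {
  set.seed(21)
  x <- rnorm(200)
  y <- rbinom(200, 1, plogis(0.5 + 1.5 * x))
  f <- fit_logistic(cbind(1, x), y)
  expect_true(all(diff(f$loglik_trace) >= -1e-10))
})

test_that("fit_logistic raises explicit errors on degenerate inputs", {
  x <- c(-2, -1, 1, 2, 3, -3)
  expect_error(fit_logistic(cbind(1, x), as.numeric(x > 0)), "separation")
  expect_error(fit_logistic(cbind(1, x), rep(1, 6)), "one-class")
  expect_error(fit_logistic(cbind(1, x), c(0, 1, 2, 0, 1, 0)), "binary")
})

test_that("disease odds ratio equals exposure odds ratio on 2x2 data", {
  for (tab in list(c(20, 30, 40, 10), c(5, 15, 25, 35), c(12, 8, 9, 21))) {
    d <- do.call(records_2x2, as.list(tab))
    f_yx <- fit_logistic(cbind(1, d$x), d$y)
    f_xy <- fit_logistic(cbind(1, d$y), d$x)
    expect_equal(unname(f_yx$estimate[2]), unname(f_xy$estimate[2]),
                 tolerance = 1e-8)
  }
})

test_that("fit_cca drops exactly the incomplete rows", {
  d <- toy_dataset(60)
  full <- fit_cca(d, spec_from_roles(d, model = "linear"))
  expect_equal(full$n, 60)
  # mask a known set of confounder cells
  d2 <- d
  d2$mask[3:9, "b"] <- TRUE
  red <- fit_cca(d2, spec_from_roles(d2, model = "linear"))
  expect_equal(red$n, 53)
  # no missing data: identical to the full fit
  expect_equal(full$estimate,
               fit_cca(d, spec_from_roles(d, model = "linear"))$estimate)
  d3 <- d
  d3$mask[1:58, "x"] <- TRUE
  expect_error(fit_cca(d3, spec_from_roles(d3, model = "linear")),
               "too few complete cases")
})

test_that("constant completeness probabilities make IPW equal CCA", {
  set.seed(31)
  d <- generate_cannabis_population(cannabis_params(n = 800, seed = 5))
  amp <- ampute(d, mechanism_spec("cannabis_use", target_rate = 0.3),
                seed = 6)
  spec <- analysis_spec("depression_21", "cannabis_use",
                        c("sex", "maternal_substance_use"), "linear")
  # weight model on a constant-free predictor set: MCAR makes p-hat nearly
  # constant, but for exact equality use an intercept-only weight model via
  # a constant column
  cca <- fit_cca(amp, spec)
  # intercept-only weight model: p-hat exactly constant, coefficients equal
  ipw0 <- fit_ipw(amp, spec, weight_predictors = character())
  expect_equal(unname(ipw0$estimate), unname(cca$estimate),
               tolerance = 1e-10)
  expect_equal(ipw0$weights_summary$cv, 0, tolerance = 1e-12)
  # an uninformative predictor leaves the weights nearly constant
  ipw <- fit_ipw(amp, spec, weight_predictors = "conduct_disorder")
  expect_equal(unname(ipw$estimate), unname(cca$estimate), tolerance = 0.05)
  expect_lt(ipw$weights_summary$cv, 0.2)
})
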