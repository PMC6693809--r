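test_that("pool_rubin matches the hand-computed m = 3 oracle to 1e-10", {
  mk <- function(est, v) fit_result("x", est, sqrt(v), df = 100, n = 100,
                                    model = "linear")
  fits <- Map(mk, c(1.0, 1.2, 1.4), c(0.04, 0.05, 0.06))
  p <- pool_rubin(fits)
  expect_equal(unname(p$estimate), 1.2, tolerance = 1e-10)
  expect_equal(unname(p$W), 0.05, tolerance = 1e-10)
  expect_equal(unname(p$B), 0.04, tolerance = 1e-10)
  expect_equal(unname(p$T), 0.05 + (4 / 3) * 0.04, tolerance = 1e-10)
  expect_equal(unname(p$df), 7.5078125, tolerance = 1e-10)
  expect_equal(unname(p$fmi), (4 / 3) * 0.04 / unname(p$T),
               tolerance = 1e-10)
})

test_that("pool_rubin degenerate and scaling properties", {
  mk <- function(est, v) fit_result(c("a", "b"), c(est, 2), sqrt(c(v, 0.1)),
                                    df = 50, n = 50, model = "linear")
  same <- pool_rubin(list(mk(1, 0.04), mk(1, 0.04), mk(1, 0.04)))
  expect_equal(unname(same$B["a"]), 0)
  expect_equal(unname(same$T["a"]), unname(same$W["a"]))
  expect_true(is.infinite(same$df["a"]))
  # doubling every variance doubles W but leaves the estimates and B alone
  f1 <- list(mk(1, 0.04), mk(1.3, 0.06))
  f2 <- list(mk(1, 0.08), mk(1.3, 0.12))
  p1 <- pool_rubin(f1); p2 <- pool_rubin(f2)
  expect_equal(p2$W["a"], 2 * p1$W["a"])
  expect_equal(p2$estimate, p1$estimate)
  expect_equal(p2$B, p1$B)
  # the Rubin identity holds for every term
  for (p in list(p1, p2, same))
    expect_equal(unname(p$T), unname(p$W + (1 + 1 / p$m) * p$B),
                 tolerance = 1e-12)
  expect_error(pool_rubin(list(mk(1, 1))), "m >= 2")
  bad <- fit_result("zzz", 1, 1, df = 5, n = 5, model = "linear")
  expect_error(pool_rubin(list(mk(1, 1), bad)), "mismatched")
})

test_that("bayesian linear draws respect zero noise and reproducibility", {
  x <- c(1, 2, 3, 4, 5, 6)
  X <- cbind(1, x)
  y <- 3 + 2 * x   # exact line
  set.seed(1)
  d <- draw_bayesian_linear(y, X, cbind(1, c(10, 20)))
  expect_equal(d$values, 3 + 2 * c(10, 20), tolerance = 1e-10)
  set.seed(5); a <- draw_bayesian_linear(rnorm(10), matrix(1, 10), matrix(1, 3))
  set.seed(5); b <- draw_bayesian_linear(rnorm(10), matrix(1, 10), matrix(1, 3))
  expect_identical(a, b)
})

test_that("intercept-only bayesian draws follow the location-scale t", {
  # marginally, a single imputation is ybar + s*sqrt(1 + 1/n)*t_{n-1}
  set.seed(33)
  n <- 9
  y <- rnorm(n, 5, 2)
  draws <- replicate(20000, draw_bayesian_linear(y, matrix(1, n),
                                                 matrix(1, 1))$values)
  qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  theo <- mean(y) + sd(y) * sqrt(1 + 1 / n) * qt(qs, n - 1)
  emp <- quantile(draws, qs)
  expect_equal(unname(emp), theo, tolerance = 0.08)
})

test_that("pmm draws come from the observed support with donor control", {
  set.seed(44)
  x <- sort(rnorm(30)); y <- 2 * x   # noiseless monotone
  X <- cbind(1, x)
  newx <- c(-0.5, 0.3)
  imp <- draw_pmm(y, X, cbind(1, newx), donors = 1)
  # donors = 1 on noiseless data returns the nearest neighbour's value
  near <- vapply(newx, function(v) y[which.min(abs(x - v))], 1)
  expect_equal(imp, near, tolerance = 1e-10)
  # always a subset of observed values, any donor count
  for (k in c(3, 30)) {
    imp <- draw_pmm(y, X, cbind(1, rnorm(20)), donors = k)
    expect_true(all(imp %in% y))
  }
  expect_error(draw_pmm(y, X, cbind(1, 0), donors = 31), "donors")
})

test_that("impute_fcs preserves observed cells and declared supports", {
  d <- generate_cannabis_population(cannabis_params(n = 300, seed = 50))
  amp <- ampute(d, list(mechanism_catalog("cannabis")$b,
                        mechanism_spec("conduct_disorder",
                                       target_rate = 0.2)), seed = 51)
  done <- impute_fcs(amp, mi_config(m = 3, iterations = 2, seed = 52))
  expect_length(done, 3)
  obs <- dataset_values(amp)
  for (cd in done) {
    v <- dataset_values(cd)
    expect_false(anyNA(v))
    # observed cells byte-identical
    for (col in names(obs)) {
      keep <- !is_missing(amp)[, col]
      expect_identical(v[[col]][keep], obs[[col]][keep])
    }
    # binary imputations in {0,1}; categorical within the level set
    expect_true(all(v$conduct_disorder %in% c(0, 1)))
    expect_true(all(v$cannabis_use %in%
                      c("none", "less_than_weekly", "weekly")))
  }
  # identical seeds give identical imputations
  again <- impute_fcs(amp, mi_config(m = 3, iterations = 2, seed = 52))
  expect_identical(lapply(done, dataset_values),
                   lapply(again, dataset_values))
})

test_that("complete data pass through MI unchanged", {
  d <- generate_cannabis_population(cannabis_params(n = 150, seed = 53))
  done <- impute_fcs(d, mi_config(m = 2, seed = 1))
  expect_identical(dataset_values(done[[1]]), dataset_values(d))
  spec <- analysis_spec("depression_21", "cannabis_use",
                        c("sex", "maternal_substance_use"), "linear")
  pooled <- mi_analyze(d, spec, mi_config(m = 3, seed = 2))
  single <- fit_cca(d, spec)
  expect_equal(pooled$estimate, single$estimate, tolerance = 1e-12)
  expect_equal(unname(pooled$B), rep(0, length(pooled$B)))
})

test_that("imputation models must include the analysis outcome", {
  d <- generate_cannabis_population(cannabis_params(n = 200, seed = 54))
  amp <- ampute(d, mechanism_catalog("cannabis")$b, seed = 55)
  spec <- analysis_spec("depression_21", "cannabis_use",
                        c("sex", "maternal_substance_use"), "linear")
  bad <- mi_config(m = 2, predictors = list(
    cannabis_use = c("sex", "maternal_substance_use")))
  expect_error(mi_analyze(amp, spec, bad), "must include the analysis outcome")
})

test_that("declared interactions are passively recomputed", {
  set.seed(60)
  n <- 200
  vals <- data.frame(y = rnorm(n), x = rnorm(n), z = rbinom(n, 1, 0.5))
  vals$xz <- vals$x * vals$z
  d <- miss_dataset(vals, roles = c(y = "outcome", x = "exposure",
                                    z = "confounder", xz = "other"))
  d$mask[sample(n, 50), "x"] <- TRUE
  done <- impute_fcs(d, mi_config(
    m = 2, iterations = 2, seed = 3,
    methods = c(x = "bayesian-linear"),
    predictors = list(x = c("y", "z")),
    derived = list(xz = c("x", "z"))))
  for (cd in done) {
    v <- dataset_values(cd)
    expect_equal(v$xz, v$x * v$z, tolerance = 1e-12)
  }
})
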