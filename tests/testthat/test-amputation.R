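test_that("classify_mechanism follows the MCAR/MAR/MNAR rules exhaustively", {
  # truth-table oracle over all parent subsets of a 5-variable system
  vars <- c("v1", "v2", "v3", "v4", ".self")
  for (k in 0:5) for (idx in utils::combn(5, k, simplify = FALSE)) {
    parents <- vars[idx]
    spec <- mechanism_spec("v9", parents = parents,
                           coefficients = rep(0.5, length(parents)),
                           target_rate = 0.3)
    oracle <- if (length(parents) == 0) "MCAR"
    else if (".self" %in% parents) "MNAR" else "MAR"
    expect_identical(classify_mechanism(spec), oracle)
  }
  # a latent-score parent is MNAR even without .self
  h <- mechanism_spec("v1", parents = "score", coefficients = 1,
                      latent = "score", target_rate = 0.3)
  expect_identical(classify_mechanism(h), "MNAR")
})

test_that("intercept calibration matches closed forms and quadrature", {
  d <- miss_dataset(data.frame(z = rnorm(100)))
  s25 <- mechanism_spec("z", target_rate = 0.25)
  expect_equal(calibrate_intercept(s25, d), qlogis(0.25), tolerance = 1e-8)
  s50 <- mechanism_spec("z", target_rate = 0.5)
  expect_equal(calibrate_intercept(s50, d), 0, tolerance = 1e-8)
  # one standard-normal parent, coefficient 1, target 0.3:
  set.seed(17)
  big <- miss_dataset(data.frame(z = rnorm(200000), z2 = 0))
  a <- calibrate_intercept(mechanism_spec("z2", parents = "z",
                                          coefficients = 1,
                                          target_rate = 0.3), big)
  # achieved empirical rate is exact to 1e-8
  expect_equal(mean(plogis(a + big$values$z)), 0.3, tolerance = 1e-8)
  # quadrature oracle: solve E_Z[plogis(a + Z)] = 0.3 over the normal density
  f <- function(a) integrate(function(z) dnorm(z) * plogis(a + z),
                             -10, 10, rel.tol = 1e-10)$value - 0.3
  a_quad <- uniroot(f, c(-5, 5), tol = 1e-10)$root
  expect_lt(abs(a - a_quad), 0.02)   # empirical vs population intercept
})

test_that("amputation alters only the mask, at the calibrated rate", {
  d <- generate_cannabis_population(cannabis_params(n = 10000, seed = 20))
  amp <- ampute(d, mechanism_catalog("cannabis")$a, seed = 21)
  expect_identical(shadow_values(amp), shadow_values(d))   # values untouched
  rate <- mean(is_missing(amp)[, "cannabis_use"])
  expect_lt(abs(rate - 0.4), 3 * sqrt(0.4 * 0.6 / 10000))
  # a floor-level intercept leaves nothing missing
  none <- ampute(d, mechanism_spec("cannabis_use", intercept = -50), seed = 1)
  expect_equal(sum(is_missing(none)), 0)
  # re-amputing an already-missing target is a contract error
  expect_error(ampute(amp, mechanism_catalog("cannabis")$a, seed = 1),
               "already has missing")
})

test_that("the mask follows the spec's logistic model and nothing else", {
  d <- generate_cannabis_population(cannabis_params(n = 100000, seed = 22))
  spec <- mechanism_catalog("cannabis")$d   # outcome + maternal substance use
  amp <- ampute(d, spec, seed = 23)
  m <- as.numeric(is_missing(amp)[, "cannabis_use"])
  v <- shadow_values(amp)
  X <- cbind(1, v$depression_21, v$maternal_substance_use, v$sex,
             v$depression_12)
  f <- fit_logistic(X, m)
  # parents recovered at their spec coefficients
  expect_lt(abs(f$estimate[2] - spec$coefficients[1]), 3 * f$se[2])
  expect_lt(abs(f$estimate[3] - spec$coefficients[2]), 3 * f$se[3])
  # non-parents estimated at zero (conditional independence given parents)
  expect_lt(abs(f$estimate[4]), 3 * f$se[4])
  expect_lt(abs(f$estimate[5]), 3 * f$se[5])
})

test_that("the catalogue encodes the documented mechanisms", {
  cat_c <- mechanism_catalog("cannabis")
  expect_equal(cat_c$a$parents, character())
  expect_identical(classify_mechanism(cat_c$a), "MCAR")
  expect_setequal(cat_c$c$parents, c("maternal_substance_use", ".self"))
  expect_identical(classify_mechanism(cat_c$c), "MNAR")
  expect_equal(cat_c$f$parents, "depression_21")
  expect_identical(classify_mechanism(cat_c$f), "MAR")
  expect_identical(classify_mechanism(cat_c$b), "MAR")
  expect_identical(classify_mechanism(cat_c$e), "MNAR")
  expect_identical(classify_mechanism(cat_c$h), "MNAR")
  # g: two independent specs, one per variable, each on its own value
  expect_length(cat_c$g, 2)
  expect_equal(cat_c$g[[1]]$parents, ".self")
  expect_equal(cat_c$g[[2]]$parents, ".self")
  # logistic variant swaps the outcome column
  expect_equal(mechanism_catalog("cannabis", outcome = "self_harm")$f$parents,
               "self_harm")
  expect_error(mechanism_catalog("nope"), "arg")
})

test_that("the growth unit mechanism produces mixed patterns at the target rate", {
  d <- generate_growth_cohort(growth_params(n = 20000, seed = 30))
  amp <- ampute(d, mechanism_catalog("growth")$complete_case, seed = 31)
  inc <- mean(!complete_cases(amp))
  target <- 404 / 951
  expect_lt(abs(inc - target), 3 * sqrt(target * (1 - target) / 20000) + 0.01)
  pt <- tabulate_patterns(amp)
  expect_gt(nrow(pt), 3)   # mixed multi-variable patterns arise
  expect_true(any(pt$confounders == "mixed"))
  # every incomplete row lost at least one block variable
  expect_true(all(rowSums(is_missing(amp)) > 0 | complete_cases(amp)))
})
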