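test_that("a fully observed dataset yields a single complete pattern", {
  d <- toy_dataset(25)
  pt <- tabulate_patterns(d)
  expect_equal(nrow(pt), 1)
  expect_equal(pt$count, 25)
  expect_equal(pt$percent, 100)
  expect_true(pt$complete_case)
})

test_that("the 951-row fixture carries the six canonical patterns", {
  d <- table3_pattern_fixture()
  expect_equal(n_rows(d), 951)
  pt <- tabulate_patterns(d)
  expect_equal(nrow(pt), 6)
  expect_equal(sum(pt$count), 951)
  expect_setequal(pt$count, c(547, 125, 7, 210, 61, 1))
  expect_setequal(round(pt$percent, 1), c(57.5, 13.1, 0.7, 22.1, 6.4, 0.1))
  expect_true(pt$complete_case[1] && pt$count[1] == 547)
  # the confounder group shows mixed observed/missing states
  p2 <- pt[pt$outcome == "observed" & pt$exposure == "observed" &
             !pt$complete_case, ]
  expect_equal(p2$count, 125)
  expect_equal(p2$confounders, "mixed")
})

test_that("pattern counts equal brute-force enumeration of mask rows", {
  set.seed(70)
  n <- 20
  vals <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  mask <- matrix(runif(n * 4) < 0.3, n, 4)
  ds <- miss_dataset(vals, roles = c(a = "outcome", b = "exposure",
                                     c = "confounder", d = "confounder"),
                     mask = mask)
  grouping <- list(a = "a", b = "b", c = "c", d = "d")
  pt <- tabulate_patterns(ds, grouping)
  oracle <- table(apply(mask, 1, paste, collapse = ""))
  expect_equal(sort(pt$count), sort(unname(as.integer(oracle))))
  expect_equal(sum(pt$count), n)
  # row order invariance
  perm <- sample(n)
  ds2 <- miss_dataset(vals[perm, , drop = FALSE],
                      roles = dataset_roles(ds), mask = mask[perm, ])
  pt2 <- tabulate_patterns(ds2, grouping)
  expect_equal(pt$count, pt2$count)
})

test_that("missingness model reproduces a hand cross-product odds ratio", {
  # binary predictor; complete/incomplete 40/10 at level 0, 20/30 at level 1
  vals <- data.frame(y = rnorm(100), x = c(rep(0, 50), rep(1, 50)))
  mask <- matrix(FALSE, 100, 2, dimnames = list(NULL, c("y", "x")))
  mask[c(41:50, 71:100), "y"] <- TRUE   # 10 and 30 incomplete
  d <- miss_dataset(vals, roles = c(y = "outcome", x = "exposure"),
                    mask = mask)
  f <- missingness_model(d, "x", analysis_vars = "y")
  expect_equal(unname(f$odds_ratio["x"]), (20 * 10) / (30 * 40),
               tolerance = 1e-6)
  expect_equal(f$n_eligible, 100)
})

test_that("missingness model recovers the growth mechanism's odds ratios", {
  d <- generate_growth_cohort(growth_params(n = 100000, seed = 80))
  amp <- ampute(d, mechanism_catalog("growth")$complete_case, seed = 81)
  preds <- c("weight_5", "birth_weight", "sex", "maternal_weight",
             "adult_bmi")
  f <- missingness_model(amp, preds)
  truth <- c(0.913, 1.19, 0.721, 0.950, 1.06)
  for (i in seq_along(preds)) {
    term <- preds[i]
    expect_lt(abs(f$estimate[term] - log(truth[i])), 3 * f$se[term])
  }
  expect_lt(f$n_eligible, n_rows(amp))   # eligibility restriction reported
})

test_that("MCAR amputation leaves all missingness-model odds ratios at 1", {
  d <- generate_cannabis_population(cannabis_params(n = 50000, seed = 82))
  amp <- ampute(d, mechanism_catalog("cannabis")$a, seed = 83)
  f <- missingness_model(amp, c("depression_21", "sex",
                                "maternal_substance_use"))
  for (term in c("depression_21", "sex", "maternal_substance_use"))
    expect_lt(abs(f$estimate[term]), 3 * f$se[term])
})

test_that("missingness model errors without incomplete cases", {
  d <- toy_dataset(30)
  expect_error(missingness_model(d, "x"), "degenerate")
})

test_that("refute_mcar flags the MAR parent and errors when complete", {
  d <- generate_cannabis_population(cannabis_params(n = 20000, seed = 84))
  amp <- ampute(d, mechanism_catalog("cannabis")$b, seed = 85)
  rep <- refute_mcar(amp, "cannabis_use")
  expect_true(rep$refuted)
  row <- rep$tests[rep$tests$candidate == "maternal_substance_use", ]
  expect_lt(row$p_value, 1e-6)
  expect_match(rep$note, "MAR from MNAR")
  expect_error(refute_mcar(d, "cannabis_use"), "no missing values")
})

test_that("refute_mcar holds its type-I error under MCAR", {
  # per-candidate rejection rate at alpha = 0.05 over replicated MCAR data
  R <- 400
  seeds <- seq_len(R)
  rej <- vapply(seeds, function(s) {
    set.seed(s)
    n <- 120
    vals <- data.frame(y = rnorm(n), x = rnorm(n))
    mask <- matrix(FALSE, n, 2, dimnames = list(NULL, c("y", "x")))
    mask[runif(n) < 0.3, "y"] <- TRUE
    d <- miss_dataset(vals, roles = c(y = "outcome", x = "exposure"),
                      mask = mask)
    refute_mcar(d, "y", candidates = "x")$refuted
  }, TRUE)
  rate <- mean(rej)
  expect_lt(abs(rate - 0.05), 2 * sqrt(0.05 * 0.95 / R))
})
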