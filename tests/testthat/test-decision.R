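test_that("bias verdicts agree with the committed golden table", {
  golden <- read.csv(system.file("extdata", "cca_verdict_golden.csv",
                                 package = "misslab"))
  expect_equal(nrow(golden), 256)
  for (i in seq_len(nrow(golden))) {
    r <- golden[i, ]
    deps <- c("outcome", "exposure", "confounders", "self")[
      c(r$outcome, r$exposure, r$confounders, r$self) == 1]
    v <- cca_bias_verdict(
      deps, model = r$model,
      true_exposure_effect_zero = r$true_exposure_effect_zero == 1,
      outcome_exposure_independent = r$outcome_exposure_independent == 1,
      dichotomized_latent = r$dichotomized_latent == 1)
    expect_identical(if (v$biased) "biased" else "unbiased", r$verdict,
                     label = paste("row", i, paste(deps, collapse = "+"),
                                   r$model))
  }
})

test_that("verdict special cases carry their rules", {
  v1 <- cca_bias_verdict("outcome", "logistic")
  expect_identical(v1$verdict, "unbiased")
  expect_match(v1$rule, "logistic-exemption")
  v2 <- cca_bias_verdict("outcome", "linear", true_exposure_effect_zero = TRUE)
  expect_identical(v2$verdict, "unbiased")
  expect_match(v2$rule, "zero-effect")
  v3 <- cca_bias_verdict(c("outcome", "exposure"), "logistic",
                         outcome_exposure_independent = TRUE)
  expect_identical(v3$verdict, "unbiased")
  expect_match(v3$rule, "independent")
  v4 <- cca_bias_verdict("outcome", "logistic", dichotomized_latent = TRUE)
  expect_true(v4$biased)
  expect_match(v4$rule, "dichotomized")
  expect_error(cca_bias_verdict("banana", "linear"), "unknown dependence")
})

test_that("incomplete-case information categories follow the pattern rules", {
  mk <- function(rows, counts) {
    n <- sum(counts)
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- c("outcome", "exposure", "confounders")
    df$count <- counts
    df$percent <- 100 * counts / n
    df$complete_case <- df$outcome == "observed" &
      df$exposure == "observed" & df$confounders == "observed"
    df <- cbind(pattern = seq_len(nrow(df)), df)
    attr(df, "n") <- n
    attr(df, "grouping") <- list(outcome = "y", exposure = "x",
                                 confounders = c("c1", "c2"))
    class(df) <- c("pattern_table", "data.frame")
    df
  }
  obs <- c("observed", "observed", "observed")
  # outcome-only missingness: no information
  p <- mk(list(obs, c("missing", "observed", "observed")), c(80, 20))
  expect_identical(incomplete_case_information(p)$category, "none")
  # exposure-only: minimal
  p <- mk(list(obs, c("observed", "missing", "observed")), c(80, 20))
  expect_identical(incomplete_case_information(p)$category, "minimal")
  # all covariates missing together: block-limited
  p <- mk(list(obs, c("observed", "missing", "missing")), c(70, 30))
  expect_identical(incomplete_case_information(p)$category, "block-limited")
  # scattered mixed patterns: substantial
  pt <- tabulate_patterns(table3_pattern_fixture())
  info <- incomplete_case_information(pt)
  expect_identical(info$category, "substantial")
  expect_equal(info$evidence$n_observed_outcome_and_exposure, 125)
  expect_match(info$guidance, "125")
})

test_that("recommendation rules reproduce the worked decisions", {
  aux_yes <- list(available = TRUE, predict_missingness = TRUE,
                  predict_values = TRUE)
  aux_no <- list(available = FALSE, predict_missingness = FALSE,
                 predict_values = FALSE)
  pt <- tabulate_patterns(table3_pattern_fixture())
  info_sub <- incomplete_case_information(pt)
  # outcome-dependent completeness + auxiliaries + substantial info -> MI
  v <- cca_bias_verdict(c("outcome", "confounders"), "linear")
  rec <- recommend_method(v, info_sub, aux_yes)
  expect_identical(rec$method, "MI")
  expect_true(all(vapply(rec$checklist, `[[`, TRUE, "pass")))
  # MNAR in the exposure with outcome-independent completeness -> CCA + warning
  v2 <- cca_bias_verdict(c("confounders", "self"), "linear")
  rec2 <- recommend_method(v2, info_sub, aux_yes, mechanism_class = "MNAR")
  expect_identical(rec2$method, "CCA")
  expect_match(paste(rec2$caveats, collapse = " "), "MAR")
  # MCAR, outcome-only missingness, no auxiliaries -> CCA
  p_none <- info_sub
  p_none$category <- "none"
  v3 <- cca_bias_verdict(character(), "linear")
  rec3 <- recommend_method(v3, p_none, aux_no)
  expect_identical(rec3$method, "CCA")
})
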