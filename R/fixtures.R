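#' Synthetic 951-row growth cohort carrying the six canonical missing-data
#' patterns
#'
#' Builds a growth cohort of 951 rows and masks the analysis variables so the
#' missing-data pattern table has exactly six patterns with counts 547, 125,
#' 7, 210, 61 and 1: the complete cases; observed outcome and exposure with
#' partially missing confounders; observed outcome with missing exposure;
#' missing outcome with complete covariates; missing outcome with partially
#' missing confounders; and missing outcome and exposure. The values are
#' synthetic (generated, then masked deterministically); only the pattern
#' structure mirrors the motivating cohort.
#'
#' @param seed RNG seed for the generated values and the row shuffle
#' @return a [miss_dataset()] of 951 rows
#' @export
table3_pattern_fixture <- function(seed = 20190316) {
  data <- generate_growth_cohort(growth_params(n = 951, seed = seed))
  counts <- c(547, 125, 7, 210, 61, 1)
  idx <- rep(seq_along(counts), counts)
  idx <- with_seed(seed + 1L, sample(idx))   # pattern labels in random rows
  mask <- data$mask
  mask[idx == 2, "paternal_weight"] <- TRUE         # confounders mixed
  mask[idx == 3, "weight_5"] <- TRUE                # exposure missing
  mask[idx == 4, "adult_bmi"] <- TRUE               # outcome missing
  mask[idx == 5, "adult_bmi"] <- TRUE               # outcome + mixed conf.
  mask[idx == 5, "paternal_weight"] <- TRUE
  mask[idx == 6, c("adult_bmi", "weight_5")] <- TRUE
  data$mask <- mask
  data
}
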