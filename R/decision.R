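#' Complete-case bias verdict for the exposure coefficient
#'
#' Encodes the bias rules for complete-case analysis of linear and logistic
#' regression as a pure function of (a) the set of analysis-variable groups
#' the chance of being a complete case depends on, (b) the model type, and
#' (c) special-case flags. The rules:
#' \itemize{
#'   \item no dependence (MCAR): unbiased for both models;
#'   \item dependence on the exposure and/or confounders only (whether MAR
#'     or MNAR, including missingness depending on the exposure's own
#'     values): unbiased for both models;
#'   \item dependence on the outcome (alone or with confounders): biased for
#'     linear regression — except when the true exposure effect is zero —
#'     and unbiased for logistic regression, because the disease odds ratio
#'     equals the exposure odds ratio;
#'   \item dependence on both the outcome and the exposure: biased for both
#'     models — except for logistic regression when the dependence acts on
#'     the outcome and the exposure independently (multiplicatively);
#'   \item none of the logistic exemptions apply when the binary outcome is
#'     a dichotomised continuous score and missingness depends on the
#'     underlying score (`dichotomized_latent`).
#' }
#'
#' @param deps character subset of `"outcome"`, `"exposure"`,
#'   `"confounders"`, `"self"` (the exposure's own missing values; treated
#'   as exposure dependence)
#' @param model `"linear"` or `"logistic"`
#' @param true_exposure_effect_zero is the true exposure coefficient zero?
#' @param outcome_exposure_independent does completeness depend on outcome
#'   and exposure through independent (multiplicative) mechanisms?
#' @param dichotomized_latent is the binary outcome a dichotomised
#'   continuous score with missingness depending on the score?
#' @return a `bias_verdict`: verdict (`"unbiased"`, `"biased"`, or
#'   `"biased-except-special-case"`), a logical `biased`, the single rule id
#'   applied, applicable special cases and a rationale string
#' @export
cca_bias_verdict <- function(deps, model = c("linear", "logistic"),
                             true_exposure_effect_zero = FALSE,
                             outcome_exposure_independent = FALSE,
                             dichotomized_latent = FALSE) {
  model <- match.arg(model)
  deps <- unique(as.character(deps))
  unknown <- setdiff(deps, c("outcome", "exposure", "confounders", "self"))
  if (length(unknown))
    stop("unknown dependence tokens: ", paste(unknown, collapse = ", "))
  deps[deps == "self"] <- "exposure"
  deps <- unique(deps)
  has_out <- "outcome" %in% deps
  has_exp <- "exposure" %in% deps

  row <- if (!length(deps)) "none"
  else if (!has_out) "exposure-confounders"
  else if (has_exp) "outcome-exposure"
  else if ("confounders" %in% deps) "outcome-confounders"
  else "outcome-only"

  mk <- function(verdict, rule, rationale, special = character()) {
    structure(list(deps = deps, model = model, verdict = verdict,
                   biased = verdict != "unbiased", rule = rule,
                   special_cases = special, rationale = rationale,
                   flags = list(
                     true_exposure_effect_zero = true_exposure_effect_zero,
                     outcome_exposure_independent = outcome_exposure_independent,
                     dichotomized_latent = dichotomized_latent)),
              class = "bias_verdict")
  }

  if (row == "none")
    return(mk("unbiased", "row-none",
              "missingness independent of the data (MCAR): complete cases representative"))
  if (row == "exposure-confounders")
    return(mk("unbiased", "row-exposure-confounders",
              "completeness does not depend on the outcome given the covariates; unbiased even under MNAR in the exposure"))
  if (model == "linear") {
    if (row == "outcome-only") {
      if (true_exposure_effect_zero)
        return(mk("unbiased", "row-outcome.footnote-zero-effect",
                  "outcome-dependent missingness, but the true exposure effect is zero, so no bias",
                  "true exposure effect zero"))
      return(mk("biased-except-special-case", "row-outcome",
                "completeness depends on the outcome: linear CCA biased (unless the true exposure effect is zero)",
                "true exposure effect zero"))
    }
    if (row == "outcome-confounders")
      return(mk("biased", "row-outcome-confounders",
                "completeness depends on the outcome after conditioning on covariates: linear CCA biased"))
    return(mk("biased", "row-outcome-exposure",
              "completeness depends on outcome and exposure: linear CCA biased"))
  }
  # logistic
  if (dichotomized_latent)
    return(mk("biased", paste0("row-", sub("-only", "", row),
                               ".dichotomized-caveat"),
              "binary outcome is a dichotomised continuous score and missingness depends on the score: the odds-ratio exemptions do not apply"))
  if (row %in% c("outcome-only", "outcome-confounders"))
    return(mk("unbiased", paste0("row-", row, ".logistic-exemption"),
              "the exposure odds ratio equals the disease odds ratio: outcome(-and-confounder)-dependent missingness leaves the logistic exposure coefficient unbiased"))
  if (outcome_exposure_independent)
    return(mk("unbiased", "row-outcome-exposure.footnote-independent",
              "completeness depends on outcome and exposure independently (multiplicatively): logistic exposure coefficient unbiased",
              "independent outcome and exposure mechanisms"))
  mk("biased-except-special-case", "row-outcome-exposure",
     "completeness depends jointly on outcome and exposure: logistic CCA biased (unless the dependence is multiplicative)",
     "independent outcome and exposure mechanisms")
}

#' @export
print.bias_verdict <- function(x, ...) {
  cat("<bias_verdict>", x$model, "model; depends on:",
      if (length(x$deps)) paste(x$deps, collapse = ", ") else "(nothing)",
      "\n  verdict:", x$verdict, " [rule ", x$rule, "]\n  ", x$rationale,
      "\n", sep = " ")
  invisible(x)
}

#' Information in the incomplete cases, by missing-data pattern
#'
#' Classifies how much information about the exposure coefficient the
#' incomplete cases are likely to contain, absent auxiliary variables:
#' \describe{
#'   \item{none}{missingness confined to the outcome — imputing the outcome
#'     gains nothing and MI standard errors tend to exceed CCA's;}
#'   \item{minimal}{missingness confined to the exposure — incomplete cases
#'     inform the confounder coefficients only;}
#'   \item{block-limited}{incomplete rows tend to lose all (or most)
#'     covariates at once, so they carry little usable information and MI is
#'     sensitive to imputation-model misspecification;}
#'   \item{substantial}{scattered missingness across variables with many
#'     partially observed rows — in particular rows with observed outcome
#'     and observed exposure — which MI can exploit for efficiency.}
#' }
#' The numeric cut-offs are configurable and reported in the output so the
#' classification can be audited.
#'
#' @param patterns a [tabulate_patterns()] result whose grouping has
#'   `outcome`, `exposure` and (optionally) `confounders` groups
#' @param block_fraction fraction of incomplete cases in all-covariates-
#'   missing patterns above which the category is `"block-limited"`
#' @return an `info_assessment`: `category`, `guidance`, `evidence`,
#'   `thresholds`
#' @export
incomplete_case_information <- function(patterns, block_fraction = 0.75) {
  stopifnot(inherits(patterns, "pattern_table"))
  n <- attr(patterns, "n")
  groups <- names(attr(patterns, "grouping"))
  inc <- patterns[!patterns$complete_case, , drop = FALSE]
  n_inc <- sum(inc$count)
  covg <- setdiff(groups, "outcome")
  ev <- list(n = n, n_incomplete = n_inc)
  mk <- function(category, guidance) {
    structure(list(category = category, guidance = guidance, evidence = ev,
                   thresholds = list(block_fraction = block_fraction)),
              class = "info_assessment")
  }
  if (n_inc == 0L)
    return(mk("none", "no incomplete cases: a plain full-data analysis applies"))
  out_only <- all(inc$outcome == "missing") &&
    all(vapply(covg, function(g) all(inc[[g]] == "observed"), TRUE))
  if (out_only)
    return(mk("none", paste(
      "only the outcome is missing: the incomplete cases carry no",
      "information about the coefficients; imputing the outcome gains",
      "nothing and MI standard errors are likely to exceed CCA's, so CCA",
      "is the best choice")))
  exp_only <- all(inc$outcome == "observed") &&
    all(inc$exposure == "missing") &&
    all(vapply(setdiff(covg, "exposure"),
               function(g) all(inc[[g]] == "observed"), TRUE))
  if (exp_only)
    return(mk("minimal", paste(
      "only the exposure is missing: incomplete cases contain minimal",
      "information about the exposure coefficient (though some about the",
      "confounders'); CCA is appropriate if interest is only in the",
      "exposure")))
  block_rows <- vapply(seq_len(nrow(inc)), function(i)
    all(vapply(covg, function(g) inc[[g]][i] == "missing", TRUE)), TRUE)
  frac_block <- sum(inc$count[block_rows]) / n_inc
  ev$fraction_covariate_block <- frac_block
  if (frac_block >= block_fraction) {
    out <- mk("block-limited", paste(
      "incomplete rows tend to lose all covariates at once: little usable",
      "information, and MI is susceptible to imputation-model",
      "misspecification; CCA may be preferred"))
    out$evidence <- ev
    return(out)
  }
  n_oe <- sum(inc$count[inc$outcome == "observed" &
                          inc$exposure == "observed"])
  ev$n_observed_outcome_and_exposure <- n_oe
  out <- mk("substantial", paste0(
    "scattered missingness with partially observed rows: ", n_oe,
    " incomplete cases have both outcome and exposure observed and are",
    " likely to contain information about the exposure coefficient; MI can",
    " use them to improve efficiency"))
  out$evidence <- ev
  out
}

#' Recommend a missing-data method
#'
#' Combines the bias verdict, the pattern-based information assessment, the
#' auxiliary-variable report and the missingness-model diagnostics into a
#' recommendation with an auditable five-point checklist:
#' (i) is CCA at risk of bias (completeness depends on the outcome)?
#' (ii) do auxiliary variables predict missingness?
#' (iii) do the incomplete cases contain usable information?
#' (iv) do auxiliary variables predict the missing values?
#' (v) is there sufficient observed information to build an imputation
#' model?
#'
#' Decision rules, applied in order: a declared MNAR mechanism whose
#' dependence excludes the outcome recommends CCA with a warning that
#' MAR-based MI would be biased (imputing such values causes bias); outcome-
#' dependent completeness, or informative auxiliaries with informative
#' incomplete cases, recommends MI; an unbiased verdict with uninformative
#' incomplete cases and no auxiliaries recommends CCA; otherwise either
#' method is defensible and IPW is noted as an adjunct when the weight model
#' is easier to specify than the imputation model.
#'
#' @param verdict a [cca_bias_verdict()] result
#' @param info an [incomplete_case_information()] result
#' @param aux list with logical fields `available`, `predict_missingness`,
#'   `predict_values` (see [auxiliary_report()])
#' @param diagnostics a [missingness_model()] fit, or `NULL`
#' @param outcome_term name of the outcome term in `diagnostics`
#' @param mechanism_class optionally the declared mechanism class
#'   (`"MCAR"`, `"MAR"`, `"MNAR"`) when the mechanism is known by design
#' @param sufficient_information is there enough observed data to build the
#'   imputation model (criterion v)?
#' @return a `recommendation`: `method` (`"CCA"`, `"MI"`, `"either"`),
#'   `checklist`, `caveats`, `rationale`
#' @export
recommend_method <- function(verdict, info, aux,
                             diagnostics = NULL, outcome_term = NULL,
                             mechanism_class = NULL,
                             sufficient_information = TRUE) {
  outcome_dependent <- "outcome" %in% verdict$deps
  if (!is.null(diagnostics) && !is.null(outcome_term)) {
    ci_excludes <- diagnostics$ci_low[outcome_term] > 0 ||
      diagnostics$ci_high[outcome_term] < 0
    outcome_dependent <- outcome_dependent || isTRUE(unname(ci_excludes))
  }
  checklist <- list(
    i_cca_bias_risk = list(
      pass = outcome_dependent || verdict$biased,
      evidence = if (outcome_dependent)
        "chance of being a complete case depends on the outcome"
      else paste("bias verdict:", verdict$verdict)),
    ii_aux_predict_missingness = list(
      pass = isTRUE(aux$available) && isTRUE(aux$predict_missingness),
      evidence = "auxiliary variables associated with completeness"),
    iii_incomplete_cases_informative = list(
      pass = info$category == "substantial",
      evidence = paste("information category:", info$category)),
    iv_aux_predict_values = list(
      pass = isTRUE(aux$available) && isTRUE(aux$predict_values),
      evidence = "auxiliary variables correlated with incomplete variables"),
    v_sufficient_information = list(
      pass = isTRUE(sufficient_information),
      evidence = "observed data sufficient for the imputation model"))
  aux_informative <- checklist$ii_aux_predict_missingness$pass ||
    checklist$iv_aux_predict_values$pass
  caveats <- character()
  if (identical(mechanism_class, "MNAR") && !outcome_dependent &&
      !verdict$biased) {
    method <- "CCA"
    caveats <- c(caveats, paste(
      "mechanism is MNAR in the exposure/confounders with outcome-",
      "independent completeness: CCA is unbiased here, but imputing the",
      "missing values under a MAR assumption would cause bias"))
    rationale <- "MNAR in covariates, outcome-independent: prefer CCA over MAR-based MI"
  } else if (outcome_dependent ||
             (aux_informative && info$category != "none")) {
    method <- "MI"
    rationale <- paste(
      "MI recommended:",
      if (outcome_dependent)
        "completeness depends on the outcome so CCA is at risk of bias;"
      else "",
      if (aux_informative)
        "auxiliary variables carry information MI can use" else "")
    if (!checklist$v_sufficient_information$pass)
      caveats <- c(caveats,
                   "observed information may be too sparse for a reliable imputation model")
  } else if (!verdict$biased && info$category %in% c("none", "minimal") &&
             !aux_informative) {
    method <- "CCA"
    rationale <- paste(
      "CCA recommended: the verdict is unbiased, the incomplete cases carry",
      if (info$category == "none") "no" else "minimal",
      "information, and there are no informative auxiliaries")
  } else {
    method <- "either"
    rationale <- paste(
      "no decisive criterion: both methods defensible; IPW is an adjunct",
      "when the completeness model is easier to specify than the",
      "imputation model")
  }
  structure(list(method = method, checklist = checklist, caveats = caveats,
                 rationale = trimws(rationale)),
            class = "recommendation")
}

#' @export
print.recommendation <- function(x, ...) {
  cat("<recommendation>", x$method, "\n")
  for (nm in names(x$checklist)) {
    it <- x$checklist[[nm]]
    cat(sprintf("  [%s] %s: %s\n", if (it$pass) "x" else " ", nm,
                it$evidence))
  }
  cat(" ", x$rationale, "\n")
  for (cv in x$caveats) cat("  caveat:", cv, "\n")
  invisible(x)
}

#' Assess the auxiliary variables of a dataset
#'
#' For each variable with role `"auxiliary"`: association with the
#' complete-case indicator (Wald test) and correlation with the observed
#' part of each incomplete analysis variable.
#'
#' @param data a [miss_dataset()]
#' @param alpha significance level
#' @return list with `available`, `predict_missingness`, `predict_values`
#'   and a per-auxiliary detail table
#' @export
auxiliary_report <- function(data, alpha = 0.05) {
  auxv <- names(data$roles)[data$roles == "auxiliary"]
  if (!length(auxv))
    return(list(available = FALSE, predict_missingness = FALSE,
                predict_values = FALSE, details = NULL))
  cc <- as.numeric(complete_cases(data))
  avars <- analysis_variables(data)
  incomplete <- avars[colSums(data$mask[, avars, drop = FALSE]) > 0L]
  rows <- lapply(auxv, function(a) {
    ok <- !data$mask[, a]
    X <- build_design(dataset_values(data, a)[ok, , drop = FALSE], a,
                      data$types)
    p_miss <- tryCatch({
      f <- fit_logistic(X, cc[ok])
      idx <- setdiff(seq_along(f$terms), 1L)
      stat <- sum((f$estimate[idx] / f$se[idx])^2)
      stats::pchisq(stat, length(idx), lower.tail = FALSE)
    }, error = function(e) NA_real_)
    p_val <- suppressWarnings(min(vapply(incomplete, function(v) {
      both <- ok & !data$mask[, v]
      if (sum(both) < 10) return(NA_real_)
      x <- numeric_column(data, a)[both]
      y <- numeric_column(data, v)[both]
      tryCatch(stats::cor.test(x, y)$p.value, error = function(e) NA_real_)
    }, numeric(1)), na.rm = TRUE))
    if (!is.finite(p_val)) p_val <- NA_real_
    data.frame(auxiliary = a, p_missingness = p_miss, p_values = p_val)
  })
  details <- do.call(rbind, rows)
  list(available = TRUE,
       predict_missingness = any(details$p_missingness < alpha,
                                 na.rm = TRUE),
       predict_values = any(details$p_values < alpha, na.rm = TRUE),
       details = details)
}
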