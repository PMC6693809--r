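#' Generator parameters for the cannabis / mental-health cohort
#'
#' Defaults define a hypothetical cohort relating self-reported cannabis use
#' at age 15 (none / less than weekly / weekly) to mental health at age 21:
#' a continuous depression symptom score and a binary self-harm indicator.
#' Confounders are the child's sex and maternal substance use; auxiliaries are
#' the child depression score at age 12 (a noisy proxy of the age-21 score)
#' and conduct disorder (associated with cannabis use). Self-harm is generated
#' through a latent logistic score (linear predictor plus standard-logistic
#' noise, dichotomised at zero), and the score is retained as a hidden latent
#' column so missingness mechanisms may depend on the underlying continuum.
#'
#' Effect sizes are chosen so that the exposure effect is large relative to
#' the outcome standard deviation (the "weekly" contrast equals one residual
#' SD) and confounder-exposure associations are moderate; every parameter can
#' be overridden.
#'
#' @param n number of individuals (>= 0)
#' @param seed RNG seed or `NULL`
#' @param outcome which outcome gets the `"outcome"` role:
#'   `"depression_21"` (linear analyses) or `"self_harm"` (logistic analyses)
#' @param ... named overrides, merged recursively into the defaults (e.g.
#'   `depression_21 = list(b_weekly = 0)`)
#' @return a `generator_params` list
#' @export
cannabis_params <- function(n = 2000, seed = NULL,
                            outcome = c("depression_21", "self_harm"), ...) {
  defaults <- list(
    example = "cannabis",
    n = n, seed = seed, outcome = match.arg(outcome),
    p_sex = 0.5,
    p_maternal_substance_use = 0.3,
    cannabis = list(b_sex = 0.4, b_msu = 0.9, cutpoints = c(0.6, 1.8)),
    depression_21 = list(intercept = 0, b_less_than_weekly = 0.5,
                         b_weekly = 1.0, b_sex = 0.3, b_msu = 0.6,
                         residual_sd = 1.0),
    self_harm = list(intercept = -1.6, b_less_than_weekly = 0.5,
                     b_weekly = 1.0, b_sex = 0.3, b_msu = 0.5),
    depression_12 = list(rho = 0.7),
    conduct_disorder = list(intercept = -1.2, b_cannabis = 0.7)
  )
  p <- utils::modifyList(defaults, list(...))
  class(p) <- "generator_params"
  validate_params(p)
  p
}

#' Generator parameters for the growth cohort
#'
#' Defaults emulate a birth-cohort follow-up in which adult body mass index
#' at age 25 is regressed on weight at age 5, adjusting for birth weight,
#' sex, gestational age (3 categories, reference 39-40 weeks), maternal and
#' paternal weight and parental socioeconomic status (3 categories, reference
#' III). The structural coefficients of the adult-BMI equation default to the
#' multiply-imputed estimates of the motivating analysis (weight-at-5 slope
#' 0.458 kg/m2 per kg, maternal weight 0.0835, paternal weight 0.0477, birth
#' weight -0.788, sex 0.165, gestational <39 weeks 0.150, >41 weeks 0.321,
#' SES I/II -0.791, SES IV/V 1.20). Auxiliary childhood anthropometry
#' (weight at 4.5 years, height at 5 years) is generated as a noisy linear
#' proxy of the exposure with configurable correlation.
#'
#' @inheritParams cannabis_params
#' @param ... named overrides merged into the defaults
#' @return a `generator_params` list
#' @export
growth_params <- function(n = 2000, seed = NULL, ...) {
  defaults <- list(
    example = "growth",
    n = n, seed = seed, outcome = "adult_bmi",
    birth_weight = list(mean = 3.4, sd = 0.5),
    p_sex = 0.5,
    # reference level first: 39-40 weeks
    gestational_age = list(levels = c("39_40", "lt39", "gt41"),
                           probs = c(0.65, 0.20, 0.15)),
    maternal_weight = list(mean = 62, sd = 10),
    paternal_weight = list(mean = 75, sd = 11),
    # reference level first: SES III
    parental_ses = list(levels = c("III", "I_II", "IV_V"),
                        probs = c(0.45, 0.30, 0.25)),
    weight_5 = list(intercept = 11, b_birth_weight = 1.5, b_sex = 0.3,
                    b_maternal_weight = 0.04, b_paternal_weight = 0.03,
                    residual_sd = 1.8),
    adult_bmi = list(intercept = 10, b_weight_5 = 0.458,
                     b_birth_weight = -0.788, b_sex = 0.165,
                     b_gest_lt39 = 0.150, b_gest_gt41 = 0.321,
                     b_maternal_weight = 0.0835, b_paternal_weight = 0.0477,
                     b_ses_I_II = -0.791, b_ses_IV_V = 1.20,
                     residual_sd = 3.2),
    weight_4_5 = list(rho = 0.7, mean = 16.5, sd = 1.7),
    height_5 = list(rho = 0.5, mean = 109, sd = 4.5)
  )
  p <- utils::modifyList(defaults, list(...))
  class(p) <- "generator_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  if (!is.numeric(p$n) || length(p$n) != 1L || p$n < 0 || p$n != floor(p$n))
    stop("n must be a nonnegative integer")
  for (nm in names(p)) {
    el <- p[[nm]]
    if (is.list(el)) {
      if (!is.null(el$residual_sd) && el$residual_sd < 0)
        stop("residual_sd must be >= 0 in block '", nm, "'")
      if (!is.null(el$sd) && el$sd < 0)
        stop("sd must be >= 0 in block '", nm, "'")
      if (!is.null(el$probs)) {
        if (any(el$probs < 0) || abs(sum(el$probs) - 1) > 1e-12)
          stop("category probabilities in block '", nm,
               "' must be nonnegative and sum to 1")
        if (length(el$probs) != length(el$levels))
          stop("probs/levels length mismatch in block '", nm, "'")
      }
      if (!is.null(el$rho) && (el$rho < -1 || el$rho > 1))
        stop("proxy correlation must lie in [-1, 1] in block '", nm, "'")
    } else if (grepl("^p_", nm)) {
      if (el < 0 || el > 1) stop(nm, " must lie in [0, 1]")
    }
  }
  invisible(p)
}

# standardise against sample moments; degenerate vectors map to zeros
z_score <- function(x) {
  if (length(x) < 2L) return(rep(0, length(x)))
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# noisy linear proxy with target correlation rho, returned on location/scale
proxy_of <- function(x, rho, mean, sd) {
  mean + sd * (rho * z_score(x) +
                 sqrt(1 - rho^2) * stats::rnorm(length(x)))
}

#' Generate the complete cannabis / mental-health cohort
#'
#' Generation follows the causal ordering: confounders (sex, maternal
#' substance use), then cannabis use from an ordinal logistic model on the
#' confounders, then the two outcomes (depression score at 21 by a linear
#' model; self-harm by a latent-logistic model), then the auxiliaries. No
#' values are missing.
#'
#' @param params a [cannabis_params()] object
#' @return a complete [miss_dataset()]; the latent self-harm score is kept as
#'   a hidden column with role `"latent"`
#' @export
generate_cannabis_population <- function(params = cannabis_params()) {
  stopifnot(inherits(params, "generator_params"),
            identical(params$example, "cannabis"))
  validate_params(params)
  p <- params
  n <- as.integer(p$n)
  with_seed(p$seed, {
    sex <- stats::rbinom(n, 1, p$p_sex)
    msu <- stats::rbinom(n, 1, p$p_maternal_substance_use)
    eta_cu <- p$cannabis$b_sex * sex + p$cannabis$b_msu * msu
    u <- stats::runif(n)
    c1 <- stats::plogis(p$cannabis$cutpoints[1] - eta_cu)
    c2 <- stats::plogis(p$cannabis$cutpoints[2] - eta_cu)
    lev <- c("none", "less_than_weekly", "weekly")
    cu <- factor(lev[1L + (u > c1) + (u > c2)], levels = lev)
    ltw <- as.numeric(cu == "less_than_weekly")
    wk <- as.numeric(cu == "weekly")
    d <- p$depression_21
    dep21 <- d$intercept + d$b_less_than_weekly * ltw + d$b_weekly * wk +
      d$b_sex * sex + d$b_msu * msu + stats::rnorm(n, 0, d$residual_sd)
    s <- p$self_harm
    sh_lp <- s$intercept + s$b_less_than_weekly * ltw + s$b_weekly * wk +
      s$b_sex * sex + s$b_msu * msu
    sh_score <- sh_lp + stats::rlogis(n)
    self_harm <- as.numeric(sh_score > 0)
    rho <- p$depression_12$rho
    dep12 <- proxy_of(dep21, rho, mean = 0, sd = 1)
    cd_lp <- p$conduct_disorder$intercept +
      p$conduct_disorder$b_cannabis * (as.numeric(cu) - 1)
    cd <- stats::rbinom(n, 1, stats::plogis(cd_lp))
    vals <- data.frame(sex = sex, maternal_substance_use = msu,
                       cannabis_use = cu, depression_21 = dep21,
                       self_harm = self_harm, self_harm_score = sh_score,
                       depression_12 = dep12, conduct_disorder = cd)
    roles <- c(sex = "confounder", maternal_substance_use = "confounder",
               cannabis_use = "exposure", depression_21 = "other",
               self_harm = "other", self_harm_score = "latent",
               depression_12 = "auxiliary", conduct_disorder = "auxiliary")
    roles[p$outcome] <- "outcome"
    types <- list(sex = list(type = "binary"),
                  maternal_substance_use = list(type = "binary"),
                  cannabis_use = list(type = "categorical", levels = lev),
                  depression_21 = list(type = "continuous"),
                  self_harm = list(type = "binary"),
                  self_harm_score = list(type = "continuous"),
                  depression_12 = list(type = "continuous"),
                  conduct_disorder = list(type = "binary"))
    miss_dataset(vals, types = types, roles = roles)
  })
}

#' Generate the complete growth cohort
#'
#' Covariates are drawn first (birth weight, sex, gestational age category,
#' parental weights, parental SES), then the exposure (weight at age 5) from
#' a linear structural equation, then the outcome (adult BMI) from the
#' structural equation whose coefficients are the generating truth, then
#' auxiliary childhood anthropometry as correlated proxies of the exposure.
#'
#' @param params a [growth_params()] object
#' @return a complete [miss_dataset()]
#' @export
generate_growth_cohort <- function(params = growth_params()) {
  stopifnot(inherits(params, "generator_params"),
            identical(params$example, "growth"))
  validate_params(params)
  p <- params
  n <- as.integer(p$n)
  with_seed(p$seed, {
    bw <- stats::rnorm(n, p$birth_weight$mean, p$birth_weight$sd)
    sex <- stats::rbinom(n, 1, p$p_sex)
    gest <- factor(sample(p$gestational_age$levels, n, replace = TRUE,
                          prob = p$gestational_age$probs),
                   levels = p$gestational_age$levels)
    mw <- stats::rnorm(n, p$maternal_weight$mean, p$maternal_weight$sd)
    pw <- stats::rnorm(n, p$paternal_weight$mean, p$paternal_weight$sd)
    ses <- factor(sample(p$parental_ses$levels, n, replace = TRUE,
                         prob = p$parental_ses$probs),
                  levels = p$parental_ses$levels)
    w <- p$weight_5
    w5 <- w$intercept + w$b_birth_weight * bw + w$b_sex * sex +
      w$b_maternal_weight * mw + w$b_paternal_weight * pw +
      stats::rnorm(n, 0, w$residual_sd)
    b <- p$adult_bmi
    bmi <- b$intercept + b$b_weight_5 * w5 + b$b_birth_weight * bw +
      b$b_sex * sex + b$b_gest_lt39 * (gest == "lt39") +
      b$b_gest_gt41 * (gest == "gt41") + b$b_maternal_weight * mw +
      b$b_paternal_weight * pw + b$b_ses_I_II * (ses == "I_II") +
      b$b_ses_IV_V * (ses == "IV_V") + stats::rnorm(n, 0, b$residual_sd)
    w45 <- proxy_of(w5, p$weight_4_5$rho, p$weight_4_5$mean, p$weight_4_5$sd)
    h5 <- proxy_of(w5, p$height_5$rho, p$height_5$mean, p$height_5$sd)
    vals <- data.frame(birth_weight = bw, sex = sex, gestational_age = gest,
                       maternal_weight = mw, paternal_weight = pw,
                       parental_ses = ses, weight_5 = w5, adult_bmi = bmi,
                       weight_4_5 = w45, height_5 = h5)
    roles <- c(birth_weight = "confounder", sex = "confounder",
               gestational_age = "confounder", maternal_weight = "confounder",
               paternal_weight = "confounder", parental_ses = "confounder",
               weight_5 = "exposure", adult_bmi = "outcome",
               weight_4_5 = "auxiliary", height_5 = "auxiliary")
    types <- list(birth_weight = list(type = "continuous"),
                  sex = list(type = "binary"),
                  gestational_age = list(type = "categorical",
                                         levels = p$gestational_age$levels),
                  maternal_weight = list(type = "continuous"),
                  paternal_weight = list(type = "continuous"),
                  parental_ses = list(type = "categorical",
                                      levels = p$parental_ses$levels),
                  weight_5 = list(type = "continuous"),
                  adult_bmi = list(type = "continuous"),
                  weight_4_5 = list(type = "continuous"),
                  height_5 = list(type = "continuous"))
    miss_dataset(vals, types = types, roles = roles)
  })
}

#' Generate one of the packaged example cohorts by name
#'
#' @param example `"cannabis"` or `"growth"`
#' @param n number of individuals
#' @param seed RNG seed
#' @param ... forwarded to the example's parameter constructor
#' @return a complete [miss_dataset()]
#' @export
generate_example <- function(example = c("cannabis", "growth"), n = 2000,
                             seed = NULL, ...) {
  example <- match.arg(example)
  switch(example,
         cannabis = generate_cannabis_population(
           cannabis_params(n = n, seed = seed, ...)),
         growth = generate_growth_cohort(
           growth_params(n = n, seed = seed, ...)))
}
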