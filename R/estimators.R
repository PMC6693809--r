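#' Analysis model specification
#'
#' Declares the main analysis: one outcome, one exposure, confounders, and
#' the model family. Categorical variables expand to reference-coded dummy
#' terms named `variable_level`; reference levels default to the first
#' declared level and are configurable via `references`.
#'
#' @param outcome outcome column name
#' @param exposure exposure column name
#' @param confounders character vector of confounder columns
#' @param model `"linear"` or `"logistic"`
#' @param references named list: categorical variable -> reference level
#' @return an `analysis_spec` object
#' @export
analysis_spec <- function(outcome, exposure, confounders = character(),
                          model = c("linear", "logistic"),
                          references = list()) {
  structure(list(outcome = outcome, exposure = exposure,
                 confounders = as.character(confounders),
                 model = match.arg(model), references = references),
            class = "analysis_spec")
}

#' Derive the analysis specification from a dataset's roles
#'
#' Requires exactly one `"outcome"` and one `"exposure"` role.
#'
#' @param data a [miss_dataset()]
#' @param model `"linear"` or `"logistic"`; default chosen by the outcome's
#'   declared type (binary -> logistic)
#' @param references named list of reference levels
#' @return an [analysis_spec()]
#' @export
spec_from_roles <- function(data, model = NULL, references = list()) {
  outc <- role_one(data, "outcome")
  expo <- role_one(data, "exposure")
  conf <- names(data$roles)[data$roles == "confounder"]
  if (is.null(model))
    model <- if (data$types[[outc]]$type == "binary") "logistic" else "linear"
  analysis_spec(outc, expo, conf, model = model, references = references)
}

# reference-coded design matrix (with intercept) from a value data.frame
build_design <- function(vals, vars, types, references = list()) {
  n <- nrow(vals)
  cols <- list("(Intercept)" = rep(1, n))
  for (v in vars) {
    tp <- types[[v]]
    if (tp$type == "categorical") {
      lev <- tp$levels
      ref <- references[[v]]
      if (is.null(ref)) ref <- lev[1]
      if (!ref %in% lev) stop("reference level '", ref,
                              "' not a level of '", v, "'")
      for (l in setdiff(lev, ref))
        cols[[paste0(v, "_", l)]] <- as.numeric(vals[[v]] == l)
    } else {
      cols[[v]] <- as.numeric(vals[[v]])
    }
  }
  do.call(cbind, cols)
}

#' Construct a regression fit result
#'
#' The common container produced by the fitting functions and consumed by
#' [pool_rubin()]: term names, estimates, standard errors and the implied
#' 95% confidence limits (t-based for linear models with `df` residual
#' degrees of freedom, normal for logistic models).
#'
#' @param terms character vector of coefficient names
#' @param estimate,se numeric vectors aligned with `terms`
#' @param df residual degrees of freedom (`Inf` for Wald/normal intervals)
#' @param n number of observations used
#' @param model `"linear"` or `"logistic"`
#' @param weights_summary optional list describing analysis weights
#' @param extra additional fields appended to the result
#' @return a `fit_result`
#' @export
fit_result <- function(terms, estimate, se, df, n, model,
                       weights_summary = NULL, extra = list()) {
  q <- if (model == "linear") stats::qt(0.975, df) else stats::qnorm(0.975)
  structure(c(list(terms = terms, estimate = stats::setNames(estimate, terms),
                   se = stats::setNames(se, terms),
                   ci_low = stats::setNames(estimate - q * se, terms),
                   ci_high = stats::setNames(estimate + q * se, terms),
                   df = df, n = n, model = model,
                   weights_summary = weights_summary), extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, digits = 4, ...) {
  cat("<fit_result> ", x$model, " model, n = ", x$n, "\n", sep = "")
  tab <- data.frame(estimate = x$estimate, se = x$se,
                    ci_low = x$ci_low, ci_high = x$ci_high)
  print(round(tab, digits))
  if (!is.null(x$weights_summary)) {
    w <- x$weights_summary
    cat(sprintf("weights: min %.3g, max %.3g, CV %.3g, %d trimmed at %.3g\n",
                w$min, w$max, w$cv, w$n_trimmed, w$floor))
    cat("variance: sandwich on fixed weights",
        "(weight-estimation uncertainty ignored; conservative)\n")
  }
  invisible(x)
}

#' Weighted least squares with explicit rank checking
#'
#' Solves the (weighted) least-squares problem by QR. Classical variance when
#' unweighted; a robust (HC0 sandwich) variance on the fixed weights when
#' weighted. Rank deficiency is an error, never silently repaired.
#'
#' @param design numeric design matrix including any intercept column
#' @param y numeric outcome vector
#' @param weights optional nonnegative weights
#' @return a `fit_result` with t-based confidence intervals
#' @export
fit_ols <- function(design, y, weights = NULL) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("design/outcome length mismatch")
  if (n <= p) stop("more parameters than observations")
  if (qr(X)$rank < p) stop("rank-deficient design")
  if (is.null(weights)) {
    fit <- stats::lm.fit(X, y)
    res <- fit$residuals
    sigma2 <- sum(res^2) / (n - p)
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(diag(XtXinv) * sigma2)
    wsum <- NULL
  } else {
    if (any(weights < 0)) stop("negative weights")
    fit <- stats::lm.wfit(X, y, weights)
    res <- y - drop(X %*% fit$coefficients)
    bread <- chol2inv(chol(crossprod(X * weights, X)))
    meat <- crossprod(X * (weights * res))
    se <- sqrt(diag(bread %*% meat %*% bread))
    wsum <- list(min = min(weights), max = max(weights),
                 cv = stats::sd(weights) / mean(weights),
                 n_trimmed = 0L, floor = NA_real_)
  }
  fit_result(colnames(X), fit$coefficients, se, df = n - p, n = n,
             model = "linear", weights_summary = wsum,
             extra = list(residual_se = sqrt(sum(
               (if (is.null(weights)) 1 else weights) * res^2) / (n - p))))
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with Newton/IRLS steps and step-halving,
#' so the log-likelihood is non-decreasing across iterations. Convergence
#' when the largest coefficient change is below `tol` (default 1e-8) within
#' `max_iter` iterations. Diverging coefficients (complete or quasi-complete
#' separation) raise an explicit error rather than returning a silent fit.
#' Classical information-based variance when unweighted; HC0 sandwich on the
#' fixed weights when weighted.
#'
#' @inheritParams fit_ols
#' @param y binary outcome in \{0, 1\}; both classes must be present
#' @param max_iter maximum IRLS iterations
#' @param tol convergence tolerance on the max absolute coefficient change
#' @return a `fit_result` (log-odds scale, Wald normal confidence intervals);
#'   the per-iteration log-likelihood trace is kept in `$loglik_trace`
#' @export
fit_logistic <- function(design, y, weights = NULL, max_iter = 100,
                         tol = 1e-8) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("design/outcome length mismatch")
  if (!all(y %in% c(0, 1))) stop("outcome must be binary in {0,1}")
  if (length(unique(y)) < 2L) stop("one-class outcome")
  if (qr(X)$rank < p) stop("rank-deficient design")
  w0 <- if (is.null(weights)) rep(1, n) else weights
  if (any(w0 < 0)) stop("negative weights")
  loglik <- function(beta) {
    eta <- drop(X %*% beta)
    # stable log(1 + exp(eta)) = max(eta, 0) + log1p(exp(-|eta|))
    sum(w0 * (y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))))
  }
  beta <- rep(0, p)
  ll <- loglik(beta)
  trace <- ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    wirls <- w0 * mu * (1 - mu)
    info <- crossprod(X * wirls, X)
    score <- drop(crossprod(X, w0 * (y - mu)))
    step <- tryCatch(solve(info, score),
                     error = function(e) stop("separation or ill-conditioned ",
                                              "information matrix: ",
                                              conditionMessage(e)))
    fac <- 1
    repeat {   # step-halving keeps the log-likelihood non-decreasing
      cand <- beta + fac * step
      llc <- loglik(cand)
      if (llc >= ll - 1e-12 || fac < 1e-8) break
      fac <- fac / 2
    }
    delta <- max(abs(cand - beta))
    beta <- cand
    ll <- llc
    trace <- c(trace, ll)
    if (max(abs(beta)) > 30)
      stop("separation detected: coefficients diverging")
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) stop("IRLS failed to converge in ", max_iter, " iterations")
  mu <- stats::plogis(drop(X %*% beta))
  wirls <- w0 * mu * (1 - mu)
  info <- crossprod(X * wirls, X)
  if (is.null(weights)) {
    se <- sqrt(diag(chol2inv(chol(info))))
    wsum <- NULL
  } else {
    bread <- chol2inv(chol(info))
    meat <- crossprod(X * (w0 * (y - mu)))
    se <- sqrt(diag(bread %*% meat %*% bread))
    wsum <- list(min = min(w0), max = max(w0),
                 cv = stats::sd(w0) / mean(w0), n_trimmed = 0L,
                 floor = NA_real_)
  }
  fit_result(colnames(X), beta, se, df = Inf, n = n, model = "logistic",
             weights_summary = wsum,
             extra = list(loglik_trace = trace, iterations = it))
}

# shared plumbing: build design + outcome for an analysis spec on given rows
model_frame <- function(data, spec, rows) {
  vars <- c(spec$outcome, spec$exposure, spec$confounders)
  vals <- dataset_values(data, vars)[rows, , drop = FALSE]
  y <- if (data$types[[spec$outcome]]$type == "categorical")
    stop("categorical outcomes are not supported") else
      as.numeric(vals[[spec$outcome]])
  X <- build_design(vals, c(spec$exposure, spec$confounders), data$types,
                    spec$references)
  list(X = X, y = y)
}

#' Complete-case analysis
#'
#' Drops every row with a missing analysis variable (outcome, exposure or
#' confounder) and fits the analysis model to the remainder.
#'
#' @param data a [miss_dataset()]
#' @param spec an [analysis_spec()]; defaults to the dataset's roles
#' @return a `fit_result`; `$n` is the complete-case count
#' @export
fit_cca <- function(data, spec = spec_from_roles(data)) {
  vars <- c(spec$outcome, spec$exposure, spec$confounders)
  cc <- complete_cases(data, vars)
  mf <- model_frame(data, spec, which(cc))
  if (sum(cc) < ncol(mf$X) + 2L)
    stop("too few complete cases (", sum(cc), ") for ", ncol(mf$X),
         " parameters")
  if (spec$model == "linear") fit_ols(mf$X, mf$y)
  else fit_logistic(mf$X, mf$y)
}

#' Inverse-probability-weighted complete-case analysis
#'
#' Fits a logistic model for the probability of being a complete case on
#' fully observed predictors, weights each complete case by the inverse of
#' its estimated probability, and refits the analysis model by weighted
#' regression with a sandwich variance on the fixed weights (weight
#' estimation uncertainty is ignored — conservative). Estimated
#' probabilities below `floor` are trimmed to `floor` and counted in the
#' reported weight summary.
#'
#' @inheritParams fit_cca
#' @param weight_predictors columns of the completeness model; must be
#'   observed on all rows
#' @param floor lower bound for estimated completeness probabilities
#' @return a `fit_result` with a `weights_summary`
#' @export
fit_ipw <- function(data, spec = spec_from_roles(data), weight_predictors,
                    floor = 0.01) {
  vars <- c(spec$outcome, spec$exposure, spec$confounders)
  cc <- complete_cases(data, vars)
  wv <- dataset_values(data, weight_predictors)
  if (anyNA(wv))
    stop("weight predictors must be fully observed")
  Xw <- build_design(wv, weight_predictors, data$types, spec$references)
  wfit <- fit_logistic(Xw, as.numeric(cc))
  phat <- stats::plogis(drop(Xw %*% wfit$estimate))
  n_trim <- sum(phat[cc] < floor)
  phat <- pmax(phat, floor)
  w <- (1 / phat)[cc]
  mf <- model_frame(data, spec, which(cc))
  fit <- if (spec$model == "linear") fit_ols(mf$X, mf$y, weights = w)
  else fit_logistic(mf$X, mf$y, weights = w)
  fit$weights_summary$n_trimmed <- n_trim
  fit$weights_summary$floor <- floor
  fit
}
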