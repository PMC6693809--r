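#' Configuration for fully-conditional-specification multiple imputation
#'
#' @param m number of imputations (>= 2)
#' @param iterations chained-equation cycles per imputation (>= 1)
#' @param methods optional named character vector mapping incomplete
#'   variables to a conditional method: `"bayesian-linear"`,
#'   `"logistic-draw"`, `"categorical-draw"` or `"pmm"`. Defaults by declared
#'   type: continuous -> pmm, binary -> logistic-draw, categorical ->
#'   categorical-draw.
#' @param predictors optional named list mapping each incomplete variable to
#'   the columns feeding its conditional model. Default: every other
#'   non-latent, non-id variable (analysis variables plus auxiliaries).
#' @param donors predictive-mean-matching donor-pool size
#' @param boot use a nonparametric bootstrap-then-fit draw for the logistic
#'   and categorical conditionals (useful in small samples) instead of the
#'   normal approximation to the coefficient posterior
#' @param derived optional named list of declared interaction terms: each
#'   element is a character vector of two column names whose product is
#'   recomputed (passively) after each imputation update, so imputation
#'   models can include analysis-model interactions consistently
#' @param seed RNG seed or `NULL`
#' @return an `mi_config` object
#' @export
mi_config <- function(m = 10, iterations = 10, methods = NULL,
                      predictors = NULL, donors = 5, boot = FALSE,
                      derived = NULL, seed = NULL) {
  if (m < 2) stop("m must be >= 2")
  if (iterations < 1) stop("iterations must be >= 1")
  if (donors < 1) stop("donors must be >= 1")
  known <- c("bayesian-linear", "logistic-draw", "categorical-draw", "pmm")
  if (!is.null(methods) && !all(methods %in% known))
    stop("unknown imputation method(s): ",
         paste(setdiff(methods, known), collapse = ", "))
  structure(list(m = as.integer(m), iterations = as.integer(iterations),
                 methods = methods, predictors = predictors,
                 donors = as.integer(donors), boot = isTRUE(boot),
                 derived = derived, seed = seed),
            class = "mi_config")
}

#' Bayesian linear-regression imputation draw
#'
#' The standard normal-linear conditional: draw the residual variance from
#' its scaled inverse chi-squared posterior, draw the coefficients from their
#' normal posterior given that variance, and return predictions for the
#' missing rows plus fresh normal noise.
#'
#' @param y_obs observed outcome values
#' @param X_obs design matrix of the observed rows (with intercept)
#' @param X_mis design matrix of the rows to impute
#' @return list with `values` (imputed values) and `beta` (the posterior
#'   coefficient draw, reused by [draw_pmm()])
#' @export
draw_bayesian_linear <- function(y_obs, X_obs, X_mis) {
  n <- length(y_obs)
  q <- ncol(X_obs)
  if (n <= q + 2L) stop("too few observed rows for a Bayesian linear draw")
  qrX <- qr(X_obs)
  if (qrX$rank < q) stop("rank-deficient imputation design")
  betahat <- qr.coef(qrX, y_obs)
  res <- y_obs - drop(X_obs %*% betahat)
  s2 <- sum(res^2) / (n - q)
  sigma2 <- (n - q) * s2 / stats::rchisq(1, n - q)
  XtXinv <- chol2inv(qr.R(qrX))
  beta <- if (sigma2 > 0)
    drop(MASS::mvrnorm(1, betahat, XtXinv * sigma2)) else betahat
  vals <- drop(X_mis %*% beta) + stats::rnorm(nrow(X_mis), 0, sqrt(sigma2))
  list(values = vals, beta = beta, sigma2 = sigma2)
}

#' Predictive-mean-matching imputation draw
#'
#' Posterior-draw linear predictions are computed for observed and missing
#' rows (one coefficient draw for both); for each missing row one of the
#' `donors` observed rows with closest predicted value is sampled uniformly
#' and that donor's *observed* value is the imputation, so imputed values
#' always lie in the observed support. Ties in predicted-value distance are
#' broken uniformly at random.
#'
#' @inheritParams draw_bayesian_linear
#' @param donors donor-pool size (>= 1, <= number of observed rows)
#' @return numeric vector of imputed values
#' @export
draw_pmm <- function(y_obs, X_obs, X_mis, donors = 5) {
  n <- length(y_obs)
  if (donors < 1 || donors > n) stop("donors must be in [1, n_obs]")
  d <- draw_bayesian_linear(y_obs, X_obs, X_mis)
  pred_obs <- drop(X_obs %*% d$beta)
  pred_mis <- drop(X_mis %*% d$beta)
  vapply(pred_mis, function(pm) {
    dist <- abs(pred_obs - pm)
    pool <- order(dist, stats::runif(n))[seq_len(donors)]
    y_obs[pool[sample.int(donors, 1L)]]
  }, numeric(1))
}

# logistic conditional: ML fit + normal coefficient perturbation (or
# bootstrap-then-fit), then Bernoulli draws
draw_logistic <- function(y_obs, X_obs, X_mis, boot = FALSE) {
  if (boot) {
    idx <- sample.int(length(y_obs), replace = TRUE)
    fit <- fit_logistic(X_obs[idx, , drop = FALSE], y_obs[idx])
    beta <- fit$estimate
  } else {
    fit <- fit_logistic(X_obs, y_obs)
    info <- crossprod(X_obs * (stats::plogis(drop(X_obs %*% fit$estimate)) *
                                 (1 - stats::plogis(drop(X_obs %*% fit$estimate)))),
                      X_obs)
    beta <- MASS::mvrnorm(1, fit$estimate, chol2inv(chol(info)))
  }
  p <- stats::plogis(drop(X_mis %*% beta))
  stats::rbinom(nrow(X_mis), 1, p)
}

# multinomial (baseline-category) logistic fit by Newton-Raphson.
# Returns coefficient matrix B (p x (K-1)) and the vec(B) covariance.
fit_multinomial <- function(X, Y, max_iter = 100, tol = 1e-8) {
  K <- ncol(Y)
  p <- ncol(X)
  n <- nrow(X)
  if (any(colSums(Y) == 0)) stop("empty outcome category")
  B <- matrix(0, p, K - 1)
  probs <- function(B) {
    ex <- exp(X %*% B)
    denom <- 1 + rowSums(ex)
    ex / denom
  }
  loglik <- function(B) {
    eta <- X %*% B
    sum(rowSums(Y[, -1, drop = FALSE] * eta) - log1p(rowSums(exp(eta))))
  }
  ll <- loglik(B)
  for (it in seq_len(max_iter)) {
    P <- probs(B)
    score <- as.vector(crossprod(X, Y[, -1, drop = FALSE] - P))
    H <- matrix(0, p * (K - 1), p * (K - 1))
    for (j in seq_len(K - 1)) for (k in j:(K - 1)) {
      wjk <- if (j == k) P[, j] * (1 - P[, j]) else -P[, j] * P[, k]
      blk <- crossprod(X * wjk, X)
      ri <- (j - 1) * p + seq_len(p)
      ci <- (k - 1) * p + seq_len(p)
      H[ri, ci] <- blk
      H[ci, ri] <- t(blk)
    }
    step <- tryCatch(solve(H, score),
                     error = function(e) stop("separation or ill-conditioned ",
                                              "multinomial information"))
    fac <- 1
    repeat {
      cand <- B + matrix(fac * step, p, K - 1)
      llc <- loglik(cand)
      if (llc >= ll - 1e-12 || fac < 1e-8) break
      fac <- fac / 2
    }
    delta <- max(abs(cand - B))
    B <- cand
    ll <- llc
    if (max(abs(B)) > 30) stop("separation detected in multinomial fit")
    if (delta < tol) {
      P <- probs(B)
      H <- matrix(0, p * (K - 1), p * (K - 1))
      for (j in seq_len(K - 1)) for (k in j:(K - 1)) {
        wjk <- if (j == k) P[, j] * (1 - P[, j]) else -P[, j] * P[, k]
        blk <- crossprod(X * wjk, X)
        ri <- (j - 1) * p + seq_len(p)
        ci <- (k - 1) * p + seq_len(p)
        H[ri, ci] <- blk
        H[ci, ri] <- t(blk)
      }
      return(list(B = B, vcov = chol2inv(chol(H)), loglik = ll))
    }
  }
  stop("multinomial fit failed to converge")
}

# categorical conditional: multinomial ML + coefficient perturbation
draw_categorical <- function(y_obs, X_obs, X_mis, boot = FALSE) {
  lev <- levels(y_obs)
  K <- length(lev)
  onehot <- function(f) {
    M <- matrix(0, length(f), K)
    M[cbind(seq_along(f), as.integer(f))] <- 1
    M
  }
  if (boot) {
    idx <- sample.int(length(y_obs), replace = TRUE)
    fit <- fit_multinomial(X_obs[idx, , drop = FALSE], onehot(y_obs[idx]))
    B <- fit$B
  } else {
    fit <- fit_multinomial(X_obs, onehot(y_obs))
    vb <- MASS::mvrnorm(1, as.vector(fit$B), fit$vcov)
    B <- matrix(vb, ncol(X_obs), K - 1)
  }
  ex <- cbind(1, exp(X_mis %*% B))
  P <- ex / rowSums(ex)
  draws <- apply(P, 1, function(pr) sample.int(K, 1L, prob = pr))
  factor(lev[draws], levels = lev)
}

default_predictors <- function(data, targets) {
  pool <- variable_names(data)
  pool <- pool[!dataset_roles(data)[pool] %in% c("id", "latent")]
  out <- lapply(targets, function(v) setdiff(pool, v))
  names(out) <- targets
  out
}

default_methods <- function(data, targets) {
  m <- vapply(targets, function(v) {
    switch(data$types[[v]]$type,
           continuous = "pmm",
           binary = "logistic-draw",
           categorical = "categorical-draw")
  }, "")
  names(m) <- targets
  m
}

#' Impute by chained equations (fully conditional specification)
#'
#' Creates `m` completed copies of the dataset. Within each imputation,
#' missing cells are initialised by random draws from the variable's observed
#' values, then the incomplete variables are visited in column order for
#' `iterations` cycles: each variable's conditional model is refitted on the
#' rows where it is observed (using the current completed values of its
#' predictors) and its missing cells redrawn. Observed cells are never
#' modified; imputed values respect the declared type (binary draws in
#' \{0,1\}, categorical draws within the level set, PMM within the observed
#' support). A conditional-model failure (separation, rank deficiency) makes
#' that variable fall back to predictive mean matching for the affected
#' draw; fallbacks are recorded in the `fallbacks` attribute.
#'
#' @param data a [miss_dataset()]
#' @param config an [mi_config()]
#' @return list of `m` completed [miss_dataset()]s (empty masks), with
#'   attribute `fallbacks` (character log, possibly empty)
#' @export
impute_fcs <- function(data, config = mi_config()) {
  stopifnot(inherits(config, "mi_config"))
  vars <- variable_names(data)
  n <- n_rows(data)
  mask <- data$mask[, vars, drop = FALSE]
  targets <- vars[colSums(mask) > 0L]
  for (v in targets)
    if (all(mask[, v])) stop("variable '", v, "' has no observed values")
  methods <- default_methods(data, targets)
  if (!is.null(config$methods))
    methods[names(config$methods)] <- config$methods
  preds <- default_predictors(data, targets)
  if (!is.null(config$predictors))
    preds[names(config$predictors)] <- config$predictors
  derived <- config$derived
  obs_vals <- dataset_values(data, vars)
  seeds <- sub_seeds(config$seed, config$m)
  fallbacks <- character()

  impute_one <- function() {
    cur <- obs_vals
    for (v in targets) {   # marginal-draw initialisation
      oo <- cur[[v]][!mask[, v]]
      cur[[v]][mask[, v]] <- oo[sample.int(length(oo), sum(mask[, v]),
                                           replace = TRUE)]
    }
    refresh_derived <- function(cur) {
      for (nm in names(derived)) {
        f <- derived[[nm]]
        cur[[nm]] <- as.numeric(cur[[f[1]]]) * as.numeric(cur[[f[2]]])
      }
      cur
    }
    cur <- refresh_derived(cur)
    if (length(targets)) for (it in seq_len(config$iterations)) {
      for (v in targets) {
        rows_mis <- mask[, v]
        pv <- setdiff(preds[[v]], v)
        X <- build_design(cur, pv, c(data$types,
                                     stats::setNames(rep(list(list(
                                       type = "continuous")), length(names(derived))),
                                       names(derived))))
        X_obs <- X[!rows_mis, , drop = FALSE]
        X_mis <- X[rows_mis, , drop = FALSE]
        y_obs <- cur[[v]][!rows_mis]
        imp <- tryCatch(
          switch(methods[[v]],
                 "bayesian-linear" =
                   draw_bayesian_linear(y_obs, X_obs, X_mis)$values,
                 "pmm" = draw_pmm(y_obs, X_obs, X_mis, config$donors),
                 "logistic-draw" =
                   draw_logistic(as.numeric(y_obs), X_obs, X_mis,
                                 config$boot),
                 "categorical-draw" =
                   draw_categorical(y_obs, X_obs, X_mis, config$boot)),
          error = function(e) {
            fallbacks <<- c(fallbacks, paste0(v, ": ", conditionMessage(e),
                                              " -> pmm fallback"))
            yo <- as.numeric(y_obs)
            pm <- draw_pmm(yo, X_obs, X_mis,
                           min(config$donors, length(yo)))
            if (data$types[[v]]$type == "categorical")
              factor(data$types[[v]]$levels[pm + 1],
                     levels = data$types[[v]]$levels)
            else pm
          })
        cur[[v]][rows_mis] <- imp
        cur <- refresh_derived(cur)
      }
    }
    miss_dataset(cur, types = data$types[vars],
                 roles = data$roles[vars])
  }

  out <- lapply(seeds, function(s) with_seed(s, impute_one()))
  attr(out, "fallbacks") <- fallbacks
  out
}

#' Pool repeated-imputation fits by Rubin's rules
#'
#' For each term: the pooled estimate is the mean of the per-imputation
#' estimates; the within-imputation variance W is the mean squared standard
#' error; the between-imputation variance B is the sample variance of the
#' estimates (divisor m - 1); the total variance is T = W + (1 + 1/m) B; the
#' large-sample degrees of freedom are (m - 1) (1 + W / ((1 + 1/m) B))^2;
#' and the fraction of missing information is (1 + 1/m) B / T. When B = 0
#' the degrees of freedom are infinite and T = W. The small-sample
#' Barnard-Rubin adjustment is available via `df_com`.
#'
#' @param fits list of `m >= 2` `fit_result`s with identical term lists
#' @param df_com optional complete-data residual degrees of freedom; when
#'   supplied the Barnard-Rubin small-sample degrees of freedom are used
#' @return a `pooled_result` with per-term `estimate`, `W`, `B`, `T`, `df`,
#'   `fmi` and 95% confidence limits from the t reference distribution
#' @export
pool_rubin <- function(fits, df_com = NULL) {
  m <- length(fits)
  if (m < 2) stop("pooling needs m >= 2 fits")
  terms <- fits[[1]]$terms
  for (f in fits)
    if (!identical(f$terms, terms)) stop("mismatched term lists across fits")
  est <- vapply(fits, function(f) f$estimate, numeric(length(terms)))
  ses <- vapply(fits, function(f) f$se, numeric(length(terms)))
  est <- matrix(est, nrow = length(terms))
  ses <- matrix(ses, nrow = length(terms))
  qbar <- rowMeans(est)
  W <- rowMeans(ses^2)
  B <- apply(est, 1, stats::var)
  Tv <- W + (1 + 1 / m) * B
  df <- ifelse(B > 0, (m - 1) * (1 + W / ((1 + 1 / m) * B))^2, Inf)
  fmi <- ifelse(Tv > 0, (1 + 1 / m) * B / Tv, 0)
  if (!is.null(df_com)) {   # Barnard-Rubin small-sample adjustment
    lam <- fmi
    df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lam)
    df <- ifelse(is.infinite(df), df_obs, 1 / (1 / df + 1 / df_obs))
  }
  q <- stats::qt(0.975, df)
  q[is.infinite(df)] <- stats::qnorm(0.975)
  structure(list(terms = terms,
                 estimate = stats::setNames(qbar, terms),
                 W = stats::setNames(W, terms),
                 B = stats::setNames(B, terms),
                 T = stats::setNames(Tv, terms),
                 se = stats::setNames(sqrt(Tv), terms),
                 df = stats::setNames(df, terms),
                 fmi = stats::setNames(fmi, terms),
                 ci_low = stats::setNames(qbar - q * sqrt(Tv), terms),
                 ci_high = stats::setNames(qbar + q * sqrt(Tv), terms),
                 m = m),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, digits = 4, ...) {
  cat("<pooled_result> m =", x$m, "imputations\n")
  print(round(data.frame(estimate = x$estimate, se = x$se, W = x$W, B = x$B,
                         T = x$T, df = x$df, fmi = x$fmi,
                         ci_low = x$ci_low, ci_high = x$ci_high), digits))
  invisible(x)
}

#' Multiply-imputed analysis
#'
#' Runs [impute_fcs()], fits the analysis model on each completed dataset
#' and pools with [pool_rubin()]. The imputation model for every incomplete
#' analysis variable must contain the analysis outcome (checked; imputation
#' models that omit the outcome bias the analysis towards the null).
#'
#' @param data a [miss_dataset()]
#' @param spec an [analysis_spec()]; defaults to the dataset's roles
#' @param config an [mi_config()]
#' @return a `pooled_result`; the configuration actually used (m,
#'   iterations, seed, predictor matrix, fallback log) is attached in
#'   `$config`
#' @export
mi_analyze <- function(data, spec = spec_from_roles(data),
                       config = mi_config()) {
  vars <- variable_names(data)
  mask <- data$mask[, vars, drop = FALSE]
  targets <- vars[colSums(mask) > 0L]
  preds <- default_predictors(data, targets)
  if (!is.null(config$predictors))
    preds[names(config$predictors)] <- config$predictors
  avars <- c(spec$outcome, spec$exposure, spec$confounders)
  for (v in intersect(targets, avars)) {
    if (v != spec$outcome && !spec$outcome %in% preds[[v]])
      stop("imputation model for analysis variable '", v,
           "' must include the analysis outcome '", spec$outcome, "'")
  }
  completed <- impute_fcs(data, config)
  fits <- lapply(completed, fit_cca, spec = spec)
  pooled <- pool_rubin(fits)
  pooled$config <- list(m = config$m, iterations = config$iterations,
                        seed = config$seed, predictors = preds,
                        methods = config$methods,
                        fallbacks = attr(completed, "fallbacks"))
  pooled
}
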