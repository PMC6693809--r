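#' Tabulate missing-data patterns by role group
#'
#' Each row of the dataset maps to exactly one pattern defined by the status
#' of each role group: `"observed"` (every variable in the group observed),
#' `"missing"` (every variable missing) or `"mixed"` (groups with two or
#' more variables, some observed and some missing). Patterns are ordered
#' with the fully observed (complete-case) pattern first, then by descending
#' count; the ordering and the counts are invariant to row order.
#'
#' @param data a [miss_dataset()]
#' @param grouping named list mapping group labels to column vectors;
#'   defaults to `outcome`, `exposure` and `confounders` from the roles
#' @return a `pattern_table`: data.frame with one status column per group,
#'   `count`, `percent` and a `complete_case` flag
#' @export
tabulate_patterns <- function(data, grouping = NULL) {
  if (is.null(grouping)) {
    grouping <- list(
      outcome = role_one(data, "outcome"),
      exposure = role_one(data, "exposure"),
      confounders = names(data$roles)[data$roles == "confounder"])
    grouping <- grouping[lengths(grouping) > 0]
  }
  n <- n_rows(data)
  status <- lapply(grouping, function(vars) {
    sub <- data$mask[, vars, drop = FALSE]
    k <- rowSums(sub)
    ifelse(k == 0L, "observed",
           ifelse(k == length(vars), "missing", "mixed"))
  })
  key <- do.call(paste, c(status, sep = "|"))
  if (n == 0L) {
    out <- data.frame(pattern = integer(), count = integer(),
                      percent = numeric(), complete_case = logical())
    class(out) <- c("pattern_table", "data.frame")
    return(out)
  }
  tab <- sort(table(key), decreasing = TRUE)
  keys <- names(tab)
  complete_key <- paste(rep("observed", length(grouping)), collapse = "|")
  keys <- c(intersect(complete_key, keys),
            setdiff(keys, complete_key))
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- names(grouping)
  out$count <- as.integer(tab[keys])
  out$percent <- 100 * out$count / n
  out$complete_case <- keys == complete_key
  out <- cbind(pattern = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "n") <- n
  attr(out, "grouping") <- grouping
  class(out) <- c("pattern_table", "data.frame")
  out
}

#' @export
print.pattern_table <- function(x, ...) {
  cat("<pattern_table> n =", attr(x, "n"), "\n")
  y <- as.data.frame(x)
  sym <- c(observed = "+", missing = "-", mixed = "+/-")
  for (g in names(attr(x, "grouping"))) y[[g]] <- sym[y[[g]]]
  y$percent <- round(y$percent, 1)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Logistic model for being a complete case
#'
#' Regresses the complete-case indicator (all analysis variables observed)
#' on the given predictors, restricted to the rows where every predictor is
#' observed — conditioning on predictor observedness changes the effective
#' sample size, so the eligible-row count is reported alongside the fit. A
#' predictor's confidence interval for its odds ratio excluding 1 is
#' evidence that the chance of being a complete case depends on it.
#'
#' @param data a [miss_dataset()]
#' @param predictors columns of the missingness model
#' @param analysis_vars variables defining completeness; defaults to the
#'   analysis variables by role
#' @return a `fit_result` (log-odds scale) with extra fields
#'   `odds_ratio`, `or_ci_low`, `or_ci_high` and `n_eligible`
#' @export
missingness_model <- function(data, predictors,
                              analysis_vars = analysis_variables(data)) {
  cc <- complete_cases(data, analysis_vars)
  vals <- dataset_values(data, predictors)
  eligible <- stats::complete.cases(vals)
  y <- as.numeric(cc[eligible])
  if (length(unique(y)) < 2L)
    stop("degenerate outcome: need both complete and incomplete cases ",
         "among the eligible rows")
  X <- build_design(vals[eligible, , drop = FALSE], predictors, data$types)
  fit <- fit_logistic(X, y)
  fit$odds_ratio <- exp(fit$estimate)
  fit$or_ci_low <- exp(fit$ci_low)
  fit$or_ci_high <- exp(fit$ci_high)
  fit$n_eligible <- sum(eligible)
  fit
}

#' Association tests refuting MCAR
#'
#' For each candidate variable, a Wald test of association between the
#' candidate and the missingness indicator of `variable` (logistic
#' regression of the indicator on the candidate, using rows where the
#' candidate is observed). A significant association refutes MCAR. A
#' non-significant result cannot distinguish MAR from MNAR: missingness may
#' still depend on the unobserved values.
#'
#' @param data a [miss_dataset()]
#' @param variable the incomplete variable whose mechanism is probed
#' @param candidates candidate predictors; defaults to all other non-latent
#'   variables
#' @param alpha significance level
#' @param adjust `"none"` (default, exploratory) or `"bonferroni"`
#' @return an `mcar_report`: per-candidate statistics, p-values, and the
#'   overall refuted flag
#' @export
refute_mcar <- function(data, variable, candidates = NULL, alpha = 0.05,
                        adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (!any(data$mask[, variable]))
    stop("variable '", variable, "' has no missing values")
  if (is.null(candidates))
    candidates <- setdiff(variable_names(data), variable)
  miss <- as.numeric(data$mask[, variable])
  rows <- lapply(candidates, function(v) {
    ok <- !data$mask[, v]
    vals <- dataset_values(data, v)[ok, , drop = FALSE]
    X <- build_design(vals, v, data$types)
    fit <- tryCatch(fit_logistic(X, miss[ok]), error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(candidate = v, statistic = NA, df = NA,
                        p_value = NA))
    idx <- setdiff(seq_along(fit$terms), 1L)   # all non-intercept terms
    b <- fit$estimate[idx]
    V <- diag(fit$se[idx]^2, nrow = length(idx))
    # per-candidate Wald: multi-df for categorical candidates
    if (length(idx) > 1L) {
      mu <- stats::plogis(drop(X %*% fit$estimate))
      info <- crossprod(X * (mu * (1 - mu)), X)
      V <- chol2inv(chol(info))[idx, idx, drop = FALSE]
    }
    stat <- drop(t(b) %*% solve(V, b))
    data.frame(candidate = v, statistic = stat, df = length(idx),
               p_value = stats::pchisq(stat, length(idx),
                                       lower.tail = FALSE))
  })
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- if (adjust == "bonferroni")
    pmin(1, tab$p_value * nrow(tab)) else tab$p_value
  tab$significant <- !is.na(tab$p_adjusted) & tab$p_adjusted < alpha
  structure(list(variable = variable, tests = tab, alpha = alpha,
                 adjust = adjust, refuted = any(tab$significant),
                 note = paste("A non-significant result does not establish",
                              "MCAR and cannot distinguish MAR from MNAR")),
            class = "mcar_report")
}

#' @export
print.mcar_report <- function(x, ...) {
  cat("<mcar_report> missingness of '", x$variable, "' (alpha = ", x$alpha,
      ", ", x$adjust, " adjustment)\n", sep = "")
  print(transform(x$tests, statistic = round(statistic, 3),
                  p_value = signif(p_value, 3),
                  p_adjusted = signif(p_adjusted, 3)), row.names = FALSE)
  cat(if (x$refuted) "MCAR refuted: observed predictors of missingness found\n"
      else "MCAR not refuted\n")
  cat(x$note, "\n")
  invisible(x)
}
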