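#' Run the full missing-data workflow: diagnose, recommend, analyse
#'
#' Reproduces the practical sequence: tabulate missing-data patterns, fit
#' the missingness model (is the chance of being a complete case associated
#' with the outcome?), probe MCAR, assess the information in the incomplete
#' cases and the auxiliary variables, derive a bias verdict from the
#' empirical dependence set, issue a recommendation, and run the chosen (or
#' forced) analysis.
#'
#' @param data a [miss_dataset()]; alternatively give `data_path` (+
#'   `roles_path`) to load from disk
#' @param data_path,roles_path CSV and YAML paths for [load_dataset()]
#' @param model `"linear"` or `"logistic"`; default from the outcome type
#' @param method `"auto"` (follow the recommendation), `"cca"`, `"ipw"` or
#'   `"mi"`
#' @param mechanism_class optionally the known mechanism class (`"MCAR"`,
#'   `"MAR"`, `"MNAR"`) when the design tells you; data alone cannot
#'   distinguish MAR from MNAR
#' @param mi an [mi_config()] for the imputation stage
#' @param weight_predictors predictors of the completeness model when
#'   `method = "ipw"`
#' @param seed run seed; every random stage draws its sub-seed from it
#' @param alpha significance level used by the diagnostic tests
#' @param out optional path: the report bundle is also written as JSON
#' @return a `workflow_report` bundle: patterns, missingness model, MCAR
#'   report, information assessment, auxiliary report, verdict,
#'   recommendation, the analysis fit, and the run log (seed, config hash,
#'   package version)
#' @export
run_workflow <- function(data = NULL, data_path = NULL, roles_path = NULL,
                         model = NULL, method = c("auto", "cca", "ipw", "mi"),
                         mechanism_class = NULL, mi = NULL,
                         weight_predictors = NULL, seed = NULL,
                         alpha = 0.05, out = NULL) {
  method <- match.arg(method)
  if (is.null(data)) {
    if (is.null(data_path)) stop("give either data or data_path")
    if (is.null(roles_path) || !file.exists(roles_path))
      stop("configuration error: roles file missing")
    data <- load_dataset(data_path, roles_path)
  }
  spec <- spec_from_roles(data, model = model)
  avars <- c(spec$outcome, spec$exposure, spec$confounders)
  seeds <- sub_seeds(seed, 2L)
  if (is.null(mi)) mi <- mi_config(seed = seeds[[1]])
  else if (is.null(mi$seed)) mi$seed <- seeds[[1]]

  n_miss <- colSums(data$mask[, avars, drop = FALSE])
  if (all(n_miss == 0)) {
    fit <- fit_cca(data, spec)
    bundle <- list(note = "no missing data among the analysis variables; plain full-data fit",
                   recommendation = list(method = "none-needed"),
                   fit = fit, seed = seed,
                   package_version = as.character(utils::packageVersion("misslab")))
    class(bundle) <- "workflow_report"
    if (!is.null(out)) write_report(bundle, out)
    return(bundle)
  }

  patterns <- tabulate_patterns(data)
  # missingness-model predictors: the outcome, the exposure and the
  # near-fully-observed confounders. Conditioning on heavily missing
  # confounders would restrict the eligible rows towards the complete cases
  # and leave the completeness indicator degenerate.
  m_preds <- c(spec$outcome, spec$exposure,
               spec$confounders[colMeans(
                 data$mask[, spec$confounders, drop = FALSE]) <= 0.05])
  mmodel <- tryCatch(missingness_model(data, predictors = m_preds),
                     error = function(e) NULL)
  worst <- avars[which.max(n_miss)]
  mcar <- refute_mcar(data, worst, alpha = alpha)
  info <- incomplete_case_information(patterns)
  aux <- auxiliary_report(data, alpha = alpha)

  deps <- character()
  if (!is.null(mmodel)) {
    terms_for <- function(v) {
      tp <- data$types[[v]]
      if (tp$type == "categorical")
        paste0(v, "_", setdiff(tp$levels, tp$levels[1])) else v
    }
    excl <- function(term) isTRUE(unname(mmodel$ci_low[term] > 0 |
                                           mmodel$ci_high[term] < 0))
    dep_on <- function(vars)
      any(vapply(intersect(unlist(lapply(vars, terms_for)), mmodel$terms),
                 excl, TRUE))
    if (dep_on(spec$outcome)) deps <- c(deps, "outcome")
    if (dep_on(spec$exposure)) deps <- c(deps, "exposure")
    if (length(spec$confounders) && dep_on(spec$confounders))
      deps <- c(deps, "confounders")
  }
  verdict <- cca_bias_verdict(deps, model = spec$model)
  enough <- all(n_miss[n_miss > 0] <= n_rows(data) - 30) &&
    sum(complete_cases(data, avars)) >= length(avars) + 5
  rec <- recommend_method(verdict, info, aux, diagnostics = mmodel,
                          outcome_term = spec$outcome,
                          mechanism_class = mechanism_class,
                          sufficient_information = enough)

  chosen <- if (method == "auto") {
    switch(rec$method, MI = "mi", CCA = "cca", either = "cca", "cca")
  } else method
  fit <- with_seed(seeds[[2]], switch(chosen,
    cca = fit_cca(data, spec),
    ipw = fit_ipw(data, spec,
                  weight_predictors = if (is.null(weight_predictors))
                    avars[n_miss == 0] else weight_predictors),
    mi = mi_analyze(data, spec, mi)))

  bundle <- list(spec = spec, patterns = patterns,
                 missingness_model = mmodel, mcar = mcar, info = info,
                 auxiliaries = aux, verdict = verdict,
                 recommendation = rec, method_used = chosen, fit = fit,
                 seed = seed, config_hash = config_hash(
                   list(spec, method, mechanism_class, seed,
                        mi[c("m", "iterations")])),
                 package_version = as.character(
                   utils::packageVersion("misslab")))
  class(bundle) <- "workflow_report"
  if (!is.null(out)) write_report(bundle, out)
  bundle
}

#' @export
print.workflow_report <- function(x, ...) {
  cat("<workflow_report>\n")
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  if (!is.null(x$patterns)) print(x$patterns)
  if (!is.null(x$verdict)) print(x$verdict)
  if (!is.null(x$recommendation)) print(x$recommendation)
  if (!is.null(x$method_used)) cat("analysis method used:", x$method_used, "\n")
  print(x$fit)
  invisible(x)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config), f)
  unname(tools::md5sum(f))
}

# strip S3 classes recursively so jsonlite serialises plain structures
strip_classes <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) {
    x <- unclass(x)
    return(lapply(x, strip_classes))
  }
  x
}

#' Write a workflow or grid report as JSON
#'
#' Numbers are serialised at full precision; the schema carries a version
#' field so downstream consumers can detect changes.
#'
#' @param bundle a report object
#' @param path output path
#' @return invisibly, the path
#' @export
write_report <- function(bundle, path) {
  payload <- list(schema_version = "1.0",
                  report = strip_classes(bundle))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
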