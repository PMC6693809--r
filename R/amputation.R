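#' Declarative missingness mechanism specification
#'
#' A `mechanism_spec` says how one target variable is made missing: a logistic
#' model on the listed parents gives each row's missingness probability. The
#' token `".self"` refers to the target's own (pre-missingness) value, which
#' makes the mechanism missing-not-at-random; parents listed in `latent` are
#' hidden continuous scores (for example the latent score underlying a
#' dichotomised outcome), which are also MNAR parents. Categorical parents
#' enter on their 0-based level code; binary parents as 0/1.
#'
#' Alternatively a unit-level (complete-case indicator) mechanism is declared
#' by supplying `block`: the logistic model then describes the probability of
#' being a *complete* case, and for each incomplete row a random non-empty
#' subset of the `block` variables is deleted, each independently with its
#' `block_probs` probability (redrawn until at least one is missing). This
#' produces mixed multi-variable missing-data patterns.
#'
#' @param target variable to make missing (ignored for unit-level specs,
#'   where it labels the complete-case indicator)
#' @param parents character vector of parent variable names; may include
#'   `".self"`
#' @param coefficients log-odds per unit of each parent (same length/order as
#'   `parents`)
#' @param intercept log-odds intercept, or `"auto"` to calibrate against
#'   `target_rate`
#' @param target_rate desired marginal missingness proportion in (0, 1)
#'   (for unit-level specs: the proportion of incomplete rows)
#' @param latent character vector naming which parents are latent scores
#' @param block for unit-level specs, the variables eligible for deletion
#' @param block_probs per-variable deletion probabilities given the row is
#'   incomplete (recycled/validated against `block`)
#' @return an object of class `mechanism_spec`
#' @export
mechanism_spec <- function(target, parents = character(),
                           coefficients = numeric(), intercept = "auto",
                           target_rate = NULL, latent = character(),
                           block = NULL, block_probs = NULL) {
  parents <- as.character(parents)
  if (length(coefficients) != length(parents))
    stop("coefficients must match parents in length")
  if (identical(intercept, "auto")) {
    if (is.null(target_rate) || target_rate <= 0 || target_rate >= 1)
      stop("target_rate must lie in (0, 1) when intercept is \"auto\"")
  } else if (!is.numeric(intercept)) {
    stop("intercept must be numeric or \"auto\"")
  }
  if (length(latent) && !all(latent %in% parents))
    stop("latent names must be a subset of parents")
  if (!is.null(block)) {
    if (is.null(block_probs)) block_probs <- rep(0.5, length(block))
    if (length(block_probs) != length(block))
      stop("block_probs must match block in length")
    if (any(block_probs < 0 | block_probs > 1))
      stop("block_probs must lie in [0, 1]")
    if (all(block_probs == 0))
      stop("at least one block_probs entry must be positive")
    if (".self" %in% parents)
      stop("unit-level specs cannot use the .self token")
  }
  structure(list(target = target, parents = parents,
                 coefficients = as.numeric(coefficients),
                 intercept = intercept, target_rate = target_rate,
                 latent = latent, block = block, block_probs = block_probs),
            class = "mechanism_spec")
}

#' @export
print.mechanism_spec <- function(x, ...) {
  kind <- if (is.null(x$block)) "cell" else "unit (complete-case indicator)"
  cat("<mechanism_spec> target:", x$target, " [", kind, "]\n")
  cat("  class:", classify_mechanism(x), "\n")
  if (length(x$parents))
    cat("  parents:", paste(sprintf("%s (%.3g)", x$parents, x$coefficients),
                            collapse = ", "), "\n")
  cat("  intercept:", if (identical(x$intercept, "auto"))
    sprintf("auto (target rate %.3g)", x$target_rate) else x$intercept, "\n")
  invisible(x)
}

#' Classify a mechanism as MCAR, MAR or MNAR
#'
#' MCAR when the mechanism has no parents; MNAR when the parents include the
#' target's own value (`".self"`) or a declared latent score; MAR otherwise
#' (missingness explained by observed variables).
#'
#' @param spec a [mechanism_spec()]
#' @return one of `"MCAR"`, `"MAR"`, `"MNAR"`
#' @export
classify_mechanism <- function(spec) {
  stopifnot(inherits(spec, "mechanism_spec"))
  if (!length(spec$parents)) return("MCAR")
  if (".self" %in% spec$parents || length(spec$latent)) return("MNAR")
  "MAR"
}

# numeric parent matrix from pre-missingness values (amputation operates on
# complete data, so .self and latent parents are available)
parent_matrix <- function(spec, data) {
  n <- n_rows(data)
  if (!length(spec$parents)) return(matrix(0, n, 0))
  cols <- lapply(spec$parents, function(pv) {
    v <- if (identical(pv, ".self")) spec$target else pv
    if (!v %in% names(data$values)) stop("unknown parent column: ", v)
    if (any(data$mask[, v]))
      stop("parent '", v, "' has missing values; amputation requires the ",
           "pre-missingness values")
    numeric_column(data, v, masked = FALSE)
  })
  do.call(cbind, cols)
}

#' Calibrate a mechanism intercept to hit a target missingness rate
#'
#' Finds the log-odds intercept `a` such that the empirical mean of
#' `plogis(a + X beta)` over the rows of `data` equals the spec's target
#' rate, by monotone root-finding (the mean probability is strictly
#' increasing in `a`). Agrees with `qlogis(rate)` when all coefficients are
#' zero.
#'
#' @param spec a [mechanism_spec()] with `intercept = "auto"`
#' @param data a [miss_dataset()] whose targeted/parent columns are complete
#' @return the calibrated intercept (log-odds), achieving the target rate
#'   within 1e-8
#' @export
calibrate_intercept <- function(spec, data) {
  stopifnot(inherits(spec, "mechanism_spec"))
  if (!identical(spec$intercept, "auto"))
    stop("spec intercept is not \"auto\"")
  if (n_rows(data) == 0L) stop("cannot calibrate an intercept on zero rows")
  rate <- if (is.null(spec$block)) spec$target_rate else 1 - spec$target_rate
  lp <- drop(parent_matrix(spec, data) %*% spec$coefficients)
  if (any(!is.finite(lp))) stop("non-finite linear predictor; cannot calibrate")
  f <- function(a) mean(stats::plogis(a + lp)) - rate
  root <- stats::uniroot(f, lower = -40, upper = 40, extendInt = "yes",
                         tol = .Machine$double.eps^0.75)$root
  if (abs(f(root)) > 1e-8)
    stop("intercept calibration failed to reach the target rate ",
         "(degenerate parent distribution?)")
  root
}

#' Impose missingness on a complete dataset
#'
#' Applies each mechanism in turn: every targeted cell is set missing
#' independently with its row's logistic probability. Observed values are
#' never altered — only the mask changes, and the pre-missingness values
#' remain readable through [shadow_values()] for simulation diagnostics.
#' Unit-level (complete-case indicator) specs instead draw row completeness
#' from the logistic model and delete a random non-empty subset of the
#' spec's `block` variables in each incomplete row.
#'
#' @param data a complete [miss_dataset()] (complete at least in the targeted
#'   variables)
#' @param specs a [mechanism_spec()] or list of them
#' @param seed RNG seed or `NULL`
#' @return the dataset with an updated mask
#' @export
ampute <- function(data, specs, seed = NULL) {
  if (inherits(specs, "mechanism_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, TRUE, "mechanism_spec")))
  n <- n_rows(data)
  with_seed(seed, {
    mask <- data$mask
    for (spec in specs) {
      lp <- drop(parent_matrix(spec, data) %*% spec$coefficients)
      if (!length(lp)) lp <- rep(0, n)
      a <- if (identical(spec$intercept, "auto")) {
        if (n == 0L) 0 else calibrate_intercept(spec, data)
      } else spec$intercept
      p <- stats::plogis(a + lp)
      if (is.null(spec$block)) {
        if (!spec$target %in% names(data$values))
          stop("unknown target column: ", spec$target)
        if (any(mask[, spec$target]))
          stop("target '", spec$target, "' already has missing values")
        hit <- stats::runif(n) < p
        mask[, spec$target] <- mask[, spec$target] | hit
      } else {
        bad <- setdiff(spec$block, names(data$values))
        if (length(bad)) stop("unknown block columns: ",
                              paste(bad, collapse = ", "))
        complete <- stats::runif(n) < p   # p is P(complete case)
        rows <- which(!complete)
        if (length(rows)) {
          sub <- matrix(stats::runif(length(rows) * length(spec$block)) <
                          rep(spec$block_probs, each = length(rows)),
                        nrow = length(rows))
          empty <- which(rowSums(sub) == 0L)
          while (length(empty)) {   # condition on at least one deletion
            sub[empty, ] <- matrix(
              stats::runif(length(empty) * length(spec$block)) <
                rep(spec$block_probs, each = length(empty)),
              nrow = length(empty))
            empty <- empty[rowSums(sub[empty, , drop = FALSE]) == 0L]
          }
          for (j in seq_along(spec$block))
            mask[rows[sub[, j]], spec$block[j]] <- TRUE
        }
      }
    }
    out <- data
    out$mask <- mask
    out
  })
}

#' Catalogue of named missingness mechanisms for the packaged examples
#'
#' For the cannabis example the catalogue encodes the six canonical
#' single-variable mechanisms for missingness in the exposure (cannabis use),
#' plus two special cases used by the simulation grid:
#' \describe{
#'   \item{a}{MCAR — no parents.}
#'   \item{b}{MAR on maternal substance use.}
#'   \item{c}{MNAR on maternal substance use and the missing cannabis values
#'     themselves.}
#'   \item{d}{MAR on the outcome and maternal substance use.}
#'   \item{e}{MNAR on the outcome and the missing cannabis values.}
#'   \item{f}{MAR on the outcome only.}
#'   \item{g}{outcome- and exposure-dependence acting *independently*: the
#'     outcome is missing depending on its own value, and cannabis use is
#'     missing depending on its own value, in two separate draws, so the
#'     complete-case probability factorises.}
#'   \item{h}{missingness of cannabis use depending on the latent continuous
#'     score underlying the dichotomised self-harm outcome.}
#' }
#' For the growth example it returns the unit-level complete-case mechanism:
#' completeness depends on weight at 5 (OR 0.913 per kg), birth weight
#' (1.19), sex (0.721), maternal weight (0.950) and adult BMI (1.06 per
#' kg/m2), and incomplete rows lose a random non-empty subset of the six
#' incompletely observed variables with probabilities proportional to the
#' motivating study's per-variable missingness counts.
#'
#' @param example `"cannabis"` or `"growth"`
#' @param outcome outcome column for the outcome-dependent cannabis
#'   mechanisms (`"depression_21"` for linear analyses, `"self_harm"` for
#'   logistic)
#' @param target_rate marginal missingness rate for the cannabis mechanisms
#'   (default 0.4); for growth, the proportion of incomplete rows (default
#'   404/951)
#' @return named list; elements are [mechanism_spec()] objects except `g`,
#'   which is a list of two specs applied jointly
#' @export
mechanism_catalog <- function(example = c("cannabis", "growth"),
                              outcome = "depression_21",
                              target_rate = NULL) {
  example <- match.arg(example)
  if (example == "cannabis") {
    r <- if (is.null(target_rate)) 0.4 else target_rate
    tg <- "cannabis_use"
    list(
      a = mechanism_spec(tg, target_rate = r),
      b = mechanism_spec(tg, parents = "maternal_substance_use",
                         coefficients = 1.2, target_rate = r),
      # the self-dependence is strong (1.5 log-odds per level) so that the
      # bias of MAR-assuming imputation is not masked by the auxiliary
      # proxies, which absorb most of a weaker dependence
      c = mechanism_spec(tg, parents = c("maternal_substance_use", ".self"),
                         coefficients = c(1.0, 1.5), target_rate = r),
      d = mechanism_spec(tg, parents = c(outcome, "maternal_substance_use"),
                         coefficients = c(0.8, 1.0), target_rate = r),
      e = mechanism_spec(tg, parents = c(outcome, ".self"),
                         coefficients = c(0.8, 0.8), target_rate = r),
      f = mechanism_spec(tg, parents = outcome, coefficients = 1.0,
                         target_rate = r),
      g = list(
        mechanism_spec(outcome, parents = ".self", coefficients = 1.2,
                       target_rate = 0.25),
        mechanism_spec(tg, parents = ".self", coefficients = 0.8,
                       target_rate = 0.3)
      ),
      # steep dependence on the latent score: the selection distortion of the
      # dichotomised outcome's regression is modest per unit, so the cell is
      # run with a strong coefficient to give the bias test its design power
      h = mechanism_spec(tg, parents = "self_harm_score",
                         coefficients = 2.0, latent = "self_harm_score",
                         target_rate = r)
    )
  } else {
    r <- if (is.null(target_rate)) 404 / 951 else target_rate
    # per-variable deletion probabilities follow the relative per-variable
    # missingness counts 272/141/45/8/3/1 among 404 incomplete rows
    blk <- c("adult_bmi", "paternal_weight", "gestational_age", "weight_5",
             "parental_ses", "maternal_weight")
    list(
      complete_case = mechanism_spec(
        "complete_case",
        parents = c("weight_5", "birth_weight", "sex", "maternal_weight",
                    "adult_bmi"),
        coefficients = log(c(0.913, 1.19, 0.721, 0.950, 1.06)),
        target_rate = r, block = blk,
        block_probs = c(272, 141, 45, 8, 3, 1) / 404)
    )
  }
}
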