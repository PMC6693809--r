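#' Rectangular dataset with a missingness mask and variable roles
#'
#' `miss_dataset` is the unit of data every stage of the package consumes and
#' produces: a rectangular table of values, a logical missingness mask of the
#' same shape (`TRUE` = missing), a declared type per column and a role per
#' column. Masked cells are unreadable through [dataset_values()]; simulation
#' code that imposed the mask itself may read the pre-missingness values
#' through [shadow_values()].
#'
#' @param values a data.frame. Continuous variables are numeric, binary
#'   variables numeric in \{0, 1\}, categorical variables factor or character.
#' @param types optional named list; each element is a list with `type` one of
#'   `"continuous"`, `"binary"`, `"categorical"` and, for categorical, a
#'   `levels` character vector. Inferred from the columns when omitted.
#' @param roles named character vector mapping column names to one of
#'   `"outcome"`, `"exposure"`, `"confounder"`, `"auxiliary"`, `"id"`,
#'   `"latent"`, `"other"`. Unlisted columns get `"other"`. Columns with role
#'   `"latent"` are hidden from analyses and from [dataset_values()].
#' @param mask logical matrix, same dimension as `values`; `TRUE` marks a
#'   missing cell. Defaults to cells that are `NA` in `values`.
#' @return an object of class `miss_dataset`.
#' @export
miss_dataset <- function(values, types = NULL, roles = NULL, mask = NULL) {
  stopifnot(is.data.frame(values))
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  nm <- names(values)
  if (is.null(types)) types <- infer_types(values)
  if (!all(nm %in% names(types)))
    stop("types missing for columns: ",
         paste(setdiff(nm, names(types)), collapse = ", "))
  # normalise storage: categorical -> factor with declared levels
  for (v in nm) {
    tp <- types[[v]]
    if (tp$type == "categorical") {
      values[[v]] <- factor(as.character(values[[v]]), levels = tp$levels)
    } else {
      values[[v]] <- as.numeric(values[[v]])
      if (tp$type == "binary") {
        ok <- is.na(values[[v]]) | values[[v]] %in% c(0, 1)
        if (!all(ok))
          stop("binary column '", v, "' has values outside {0,1}")
      }
    }
  }
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(values), ncol(values))
    for (j in seq_along(values)) mask[, j] <- is.na(values[[j]])
  }
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(values)))
    stop("mask shape must equal values shape")
  dimnames(mask) <- list(NULL, nm)
  storage.mode(mask) <- "logical"
  rl <- rep("other", length(nm)); names(rl) <- nm
  if (!is.null(roles)) {
    unknown <- setdiff(names(roles), nm)
    if (length(unknown))
      stop("roles refer to unknown columns: ", paste(unknown, collapse = ", "))
    bad <- setdiff(roles, c("outcome", "exposure", "confounder", "auxiliary",
                            "id", "latent", "other"))
    if (length(bad)) stop("unknown roles: ", paste(bad, collapse = ", "))
    rl[names(roles)] <- roles
  }
  structure(list(values = values, mask = mask, types = types, roles = rl),
            class = "miss_dataset")
}

infer_types <- function(values) {
  out <- lapply(values, function(col) {
    if (is.factor(col))
      return(list(type = "categorical", levels = levels(col)))
    if (is.character(col))
      return(list(type = "categorical",
                  levels = sort(unique(col[!is.na(col)]))))
    u <- unique(col[!is.na(col)])
    if (length(u) && all(u %in% c(0, 1))) list(type = "binary")
    else list(type = "continuous")
  })
  names(out) <- names(values)
  out
}

#' @export
print.miss_dataset <- function(x, ...) {
  cat("<miss_dataset> ", nrow(x$values), " rows x ", ncol(x$values),
      " variables\n", sep = "")
  pm <- if (nrow(x$values)) round(100 * colMeans(x$mask), 1) else
    rep(0, ncol(x$values))
  info <- data.frame(role = x$roles,
                     type = vapply(x$types[names(x$values)],
                                   function(t) t$type, ""),
                     pct_missing = pm)
  print(info, ...)
  invisible(x)
}

#' Number of rows of a dataset
#' @param data a [miss_dataset()]
#' @return integer row count
#' @export
n_rows <- function(data) nrow(data$values)

#' Column names of a dataset
#' @inheritParams n_rows
#' @param include_latent include columns with role `"latent"`?
#' @return character vector
#' @export
variable_names <- function(data, include_latent = FALSE) {
  nm <- names(data$values)
  if (!include_latent) nm <- nm[data$roles[nm] != "latent"]
  nm
}

#' Variable roles
#' @inheritParams n_rows
#' @return named character vector of roles
#' @export
dataset_roles <- function(data) data$roles

#' Replace variable roles
#' @inheritParams n_rows
#' @param value named character vector of roles to set
#' @return the modified dataset
#' @export
`dataset_roles<-` <- function(data, value) {
  miss_dataset(shadow_values(data), types = data$types,
               roles = replace(data$roles, names(value), value),
               mask = data$mask)
}

#' Observed values of a dataset
#'
#' The public accessor: masked cells are returned as `NA`, and latent columns
#' are dropped. Use this for any analysis.
#'
#' @inheritParams n_rows
#' @param vars optional subset of columns
#' @return data.frame with `NA` in masked cells
#' @export
dataset_values <- function(data, vars = NULL) {
  if (is.null(vars)) vars <- variable_names(data)
  hidden <- vars[data$roles[vars] == "latent"]
  if (length(hidden))
    stop("latent columns are not readable: ", paste(hidden, collapse = ", "))
  out <- data$values[, vars, drop = FALSE]
  for (v in vars) out[[v]][data$mask[, v]] <- NA
  out
}

#' Pre-missingness values (simulation truth)
#'
#' Returns the underlying table ignoring the mask. Only meaningful when the
#' mask was imposed by [ampute()] on complete data; for data loaded from disk
#' the masked cells are genuinely unknown (`NA`).
#'
#' @inheritParams n_rows
#' @return data.frame of underlying values
#' @export
shadow_values <- function(data) data$values

#' Missingness mask
#' @inheritParams n_rows
#' @return logical matrix, `TRUE` = missing
#' @export
is_missing <- function(data) data$mask

#' Complete-case indicator over a set of variables
#' @inheritParams n_rows
#' @param vars variables that must all be observed; defaults to the analysis
#'   variables (roles outcome, exposure, confounder)
#' @return logical vector, `TRUE` when every `vars` cell in the row is observed
#' @export
complete_cases <- function(data, vars = NULL) {
  if (is.null(vars)) vars <- analysis_variables(data)
  rowSums(data$mask[, vars, drop = FALSE]) == 0L
}

#' Analysis variables by role
#' @inheritParams n_rows
#' @return character vector: the outcome, exposure and confounder columns
#' @export
analysis_variables <- function(data) {
  names(data$roles)[data$roles %in% c("outcome", "exposure", "confounder")]
}

# role lookup with uniqueness checks used whenever an analysis is requested
role_one <- function(data, role) {
  v <- names(data$roles)[data$roles == role]
  if (length(v) != 1L)
    stop("exactly one '", role, "' role required, found ", length(v))
  v
}

#' Numeric coding of a column
#'
#' Continuous and binary columns are returned as stored; categorical columns
#' are coded 0, 1, 2, ... by level order. Used by missingness models, which
#' act on a per-unit log-odds scale.
#'
#' @inheritParams n_rows
#' @param var column name
#' @param masked apply the mask (`NA` where missing)?
#' @return numeric vector
#' @export
numeric_column <- function(data, var, masked = TRUE) {
  col <- data$values[[var]]
  out <- if (is.factor(col)) as.numeric(col) - 1 else as.numeric(col)
  if (masked) out[data$mask[, var]] <- NA
  out
}
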