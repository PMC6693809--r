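#' Read a dataset from CSV with a YAML roles/types sidecar
#'
#' The CSV must have a header row; cells equal to one of the `na` sentinels
#' (after trimming nothing — matches are exact) are treated as missing. The
#' sidecar declares per-column roles and types; columns absent from the
#' sidecar get role `"other"` and an inferred type.
#'
#' @param path CSV file path
#' @param roles_path YAML sidecar path; optional. Keys: `roles` (name: role)
#'   and `types` (name: either a type string or a map with `type` and
#'   `levels`).
#' @param na character vector of missing-value sentinels (default `""` and
#'   `"NA"`)
#' @return a [miss_dataset()]
#' @export
load_dataset <- function(path, roles_path = NULL, na = c("", "NA")) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, stringsAsFactors = FALSE)
  roles <- NULL
  types <- NULL
  if (!is.null(roles_path)) {
    if (!file.exists(roles_path)) stop("roles file not found: ", roles_path)
    side <- yaml::read_yaml(roles_path)
    if (!is.null(side$roles)) {
      roles <- unlist(side$roles)
      unknown <- setdiff(names(roles), names(raw))
      if (length(unknown))
        stop("roles file names unknown columns: ",
             paste(unknown, collapse = ", "))
    }
    if (!is.null(side$types)) {
      types <- lapply(side$types, function(t) {
        if (is.character(t) && length(t) == 1L) list(type = t)
        else list(type = t$type, levels = unlist(t$levels))
      })
    }
  }
  vals <- raw
  for (v in names(vals)) {
    cell_na <- vals[[v]] %in% na | is.na(vals[[v]])
    tp <- types[[v]]
    if (is.null(tp) || tp$type %in% c("continuous", "binary")) {
      num <- suppressWarnings(as.numeric(vals[[v]]))
      bad <- which(!cell_na & is.na(num))
      if (length(bad)) {
        if (!is.null(tp))
          stop("non-numeric value in ", tp$type, " column '", v,
               "' at row ", bad[1], ": '", vals[[v]][bad[1]], "'")
        # undeclared column with non-numeric entries: treat as categorical
        vals[[v]][cell_na] <- NA
        next
      }
      num[cell_na] <- NA
      vals[[v]] <- num
    } else {
      x <- vals[[v]]
      x[cell_na] <- NA
      bad <- which(!is.na(x) & !x %in% tp$levels)
      if (length(bad))
        stop("value outside declared levels in column '", v, "' at row ",
             bad[1], ": '", x[bad[1]], "'")
      vals[[v]] <- factor(x, levels = tp$levels)
    }
  }
  if (is.null(types)) types <- infer_types(vals)
  else {
    miss <- setdiff(names(vals), names(types))
    types <- c(types, infer_types(vals[miss]))
  }
  miss_dataset(vals, types = types, roles = roles)
}

#' Write a dataset to CSV with a YAML roles/types sidecar
#'
#' Masked cells are written as empty strings. Latent columns are not written.
#'
#' @param data a [miss_dataset()]
#' @param path CSV output path
#' @param roles_path YAML sidecar output path; default `path` with a `.yaml`
#'   extension
#' @return invisibly, the CSV path
#' @export
write_dataset <- function(data, path,
                          roles_path = paste0(sub("\\.csv$", "", path),
                                              ".yaml")) {
  vars <- variable_names(data)
  vals <- dataset_values(data, vars)
  out <- lapply(vals, function(col) {
    s <- as.character(col)
    s[is.na(s)] <- ""
    s
  })
  utils::write.csv(as.data.frame(out, check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  side <- list(
    roles = as.list(data$roles[vars]),
    types = lapply(data$types[vars], function(t) {
      if (t$type == "categorical") list(type = t$type,
                                        levels = as.list(t$levels))
      else t$type
    })
  )
  yaml::write_yaml(side, roles_path)
  invisible(path)
}
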