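new_bundle <- function(table, variable_specs, provenance, params = NULL,
                       formula = NULL) {
  structure(list(table = table, variable_specs = variable_specs,
                 provenance = provenance, params = params, formula = formula),
            class = "dn_bundle")
}

#' @export
print.dn_bundle <- function(x, ...) {
  cat(sprintf("<dataset bundle> %d rows x %d cols (%s)\n", nrow(x$table),
              ncol(x$table), x$provenance))
  for (s in x$variable_specs) print(s)
  invisible(x)
}

#' Read a CSV dataset with a role sidecar
#'
#' Reads a headered CSV and types each declared column by its role:
#' covariates and time become numeric, status numeric 0/1, factors become
#' character labels (a numeric column declared as a factor uses its distinct
#' values as labels). The sidecar is YAML or JSON of the form
#' `columns: {age: {role: covariate}, sex: {role: factor, levels: [m, f]}}`;
#' undeclared columns are kept untyped. Variable specifications (ranges,
#' levels, mean, mode) are computed from the typed table.
#'
#' @param csv_path CSV file with a header row.
#' @param sidecar_path optional YAML/JSON sidecar; or pass a list via
#'   `config`.
#' @param config optional config list (overrides `sidecar_path`).
#' @return a `dn_bundle` with `table`, `variable_specs`,
#'   `provenance = "user"`.
#' @export
read_dataset <- function(csv_path, sidecar_path = NULL, config = NULL) {
  tab <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (is.null(config) && !is.null(sidecar_path)) {
    config <- if (grepl("\\.json$", sidecar_path, ignore.case = TRUE))
      jsonlite::fromJSON(sidecar_path, simplifyVector = FALSE)
    else yaml::read_yaml(sidecar_path)
  }
  cols <- config$columns %||% list()
  missing_cols <- setdiff(names(cols), names(tab))
  if (length(missing_cols))
    stop("declared column(s) absent from CSV: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  roles <- list(); level_order <- list()
  for (nm in names(cols)) {
    role <- cols[[nm]]$role
    roles[[nm]] <- role
    x <- tab[[nm]]
    if (role %in% c("covariate", "time", "status")) {
      xn <- suppressWarnings(as.numeric(x))
      bad <- which(is.na(xn) & !is.na(x) & x != "")
      if (length(bad))
        stop("cannot coerce column '", nm, "' to numeric at row(s) ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      tab[[nm]] <- xn
    } else if (role == "factor") {
      tab[[nm]] <- as.character(x)
      if (!is.null(cols[[nm]]$levels))
        level_order[[nm]] <- unlist(cols[[nm]]$levels)
    } else stop("unknown role '", role, "' for column '", nm, "'",
                call. = FALSE)
  }
  typed <- names(roles)
  keep <- stats::complete.cases(tab[typed])
  specs <- specs_from_data(tab[keep, , drop = FALSE], typed, roles, level_order)
  new_bundle(tab, specs, "user",
             params = list(level_order = level_order, roles = roles))
}

#' Write a bundle back to CSV + sidecar
#'
#' @param bundle a `dn_bundle`.
#' @param csv_path output CSV.
#' @param sidecar_path optional output YAML sidecar declaring roles and
#'   level orders.
#' @return `csv_path`, invisibly.
#' @export
write_dataset <- function(bundle, csv_path, sidecar_path = NULL) {
  utils::write.csv(bundle$table, csv_path, row.names = FALSE)
  if (!is.null(sidecar_path)) {
    cols <- lapply(bundle$variable_specs, function(s) {
      out <- list(role = s$role)
      if (!is.null(s$levels)) out$levels <- as.list(s$levels)
      out
    })
    yaml::write_yaml(list(columns = cols), sidecar_path)
  }
  invisible(csv_path)
}
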