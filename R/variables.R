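#' Describe one model variable
#'
#' A variable specification records what the engine needs to know about a
#' column at prediction and layout time: its role, and either its observed
#' numeric support (covariates) or its level set (factors). Slider bounds in
#' the dynamic interface and ruler extents in the static nomogram both come
#' from these frozen specifications, so they are captured once, at fit time.
#'
#' @param name column name in the data.
#' @param role one of `"covariate"`, `"factor"`, `"time"`, `"status"`.
#' @param levels ordered character vector of levels (factors only); the first
#'   level is the reference.
#' @param observed_min,observed_max numeric support (covariates only).
#' @param mean observed mean (covariates); used as the default slider value.
#' @param mode most frequent level (factors); used as the default selection.
#' @return an object of class `dn_variable`.
#' @export
variable_spec <- function(name, role, levels = NULL, observed_min = NULL,
                          observed_max = NULL, mean = NULL, mode = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  role <- match.arg(role, c("covariate", "factor", "time", "status"))
  if (role == "factor") {
    if (is.null(levels) || length(unique(levels)) < 2L)
      stop("factor variable '", name, "' needs at least 2 distinct levels",
           call. = FALSE)
    levels <- as.character(levels)
    if (anyDuplicated(levels))
      stop("duplicate levels for factor '", name, "'", call. = FALSE)
    if (!is.null(mode) && !(mode %in% levels))
      stop("mode '", mode, "' is not a level of factor '", name, "'",
           call. = FALSE)
  }
  if (role == "covariate") {
    if (!is.null(observed_min) && !is.null(observed_max) && !is.null(mean)) {
      if (!(observed_min <= mean && mean <= observed_max))
        stop("covariate '", name, "': mean must lie within [observed_min, observed_max]",
             call. = FALSE)
    }
  }
  structure(list(name = name, role = role, levels = levels,
                 observed_min = observed_min, observed_max = observed_max,
                 mean = mean, mode = mode),
            class = "dn_variable")
}

# compute frozen variable specs from observed (complete-case) data.
# level_order: optional named list of explicit level orderings; otherwise
# levels are the lexicographically sorted observed labels, first = reference.
specs_from_data <- function(data, vars, roles, level_order = list()) {
  out <- list()
  for (v in vars) {
    x <- data[[v]]
    role <- roles[[v]]
    if (role %in% c("covariate", "time", "status")) {
      x <- as.numeric(x)
      if (role == "covariate") {
        out[[v]] <- variable_spec(v, "covariate",
                                  observed_min = min(x), observed_max = max(x),
                                  mean = base::mean(x))
      } else {
        out[[v]] <- variable_spec(v, role)
      }
    } else {
      labs <- as.character(x)
      obs <- sort(unique(labs))
      lev <- level_order[[v]] %||% obs
      if (!all(obs %in% lev))
        stop("declared levels for '", v, "' omit observed label(s): ",
             paste(setdiff(obs, lev), collapse = ", "), call. = FALSE)
      if (length(obs) < 2L)
        stop("factor '", v, "' collapses to a single observed level", call. = FALSE)
      tab <- table(labs)
      # mode = most frequent observed level, ties broken lexicographically
      mode <- sort(names(tab)[tab == max(tab)])[1L]
      out[[v]] <- variable_spec(v, "factor", levels = lev, mode = mode)
    }
  }
  out
}

#' @export
print.dn_variable <- function(x, ...) {
  if (x$role == "covariate")
    cat(sprintf("<variable> %s: covariate on [%g, %g], mean %g\n",
                x$name, x$observed_min, x$observed_max, x$mean))
  else if (x$role == "factor")
    cat(sprintf("<variable> %s: factor {%s}, mode %s\n",
                x$name, paste(x$levels, collapse = ", "), x$mode))
  else
    cat(sprintf("<variable> %s: %s\n", x$name, x$role))
  invisible(x)
}
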