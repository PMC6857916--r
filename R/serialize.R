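# terms and variable specs serialize to plain lists so the model JSON is
# self-describing and a bundle never needs the training data

term_to_list <- function(t) {
  list(kind = t$kind, vars = as.list(t$vars),
       k = t$k, knots = if (!is.null(t$knots)) as.numeric(t$knots))
}

term_from_list <- function(l) {
  switch(l$kind,
         covariate = term_covariate(l$vars[[1]]),
         factor = term_factor(l$vars[[1]]),
         spline = term_spline(l$vars[[1]], k = l$k, knots = as.numeric(l$knots)),
         interaction = term_interaction(unlist(l$vars)),
         stop("unknown term kind: ", l$kind, call. = FALSE))
}

spec_to_list <- function(s) {
  list(name = s$name, role = s$role,
       levels = if (!is.null(s$levels)) as.list(s$levels),
       observed_min = s$observed_min, observed_max = s$observed_max,
       mean = s$mean, mode = s$mode)
}

spec_from_list <- function(l) {
  variable_spec(l$name, l$role,
                levels = if (!is.null(l$levels)) unlist(l$levels),
                observed_min = l$observed_min, observed_max = l$observed_max,
                mean = l$mean, mode = l$mode)
}

#' Serialize a fitted model to JSON
#'
#' Writes everything prediction and layout need (coefficients, covariance,
#' family/link, dispersion, frozen variable specifications and spline knots,
#' and for Cox models the baseline hazard table) so the model can be
#' re-imported and used without the training data.
#'
#' @param model a fitted `dn_model`.
#' @param path output file; when `NULL` the JSON string is returned.
#' @return `path` (invisibly), or the JSON string when `path` is `NULL`.
#' @export
export_model <- function(model, path = NULL) {
  stopifnot(inherits(model, "dn_model"))
  obj <- list(
    format = "dynogram-model", version = 1L,
    family = model$family, link = model$link,
    response = model$formula$response,
    time = model$formula$time, status = model$formula$status,
    columns = as.list(model$column_labels),
    beta = as.numeric(model$beta),
    sigma = unname(apply(model$sigma, 1L, as.numeric, simplify = FALSE)),
    dispersion = model$dispersion, df_residual = model$df_residual,
    n_used = model$n_used, n_dropped = model$n_dropped, loglik = model$loglik,
    has_intercept = model$has_intercept,
    terms = lapply(model$terms, term_to_list),
    level_order = model$formula$level_order,
    variable_specs = lapply(model$variable_specs, spec_to_list))
  if (inherits(model, "dn_cox")) {
    obj$cox <- list(
      ties = model$ties, covariate_means = as.numeric(model$covariate_means),
      n_events = model$n_events, max_follow_up = model$max_follow_up,
      baseline = list(time = model$baseline$time,
                      n_event = model$baseline$n_event,
                      n_risk = model$baseline$n_risk,
                      s0 = model$baseline$s0,
                      cumhaz = model$baseline$cumhaz,
                      s1 = unname(apply(matrix(model$baseline$s1,
                                               nrow = nrow(model$baseline)),
                                        1L, as.numeric, simplify = FALSE))))
  }
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17), null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Import a serialized model
#'
#' Reads a JSON file written by [export_model()] (or assembled by hand for an
#' externally fitted model) and returns a `dn_model` usable by the
#' prediction, layout and app layers without refitting. Dimensions and the
#' symmetry of the covariance matrix are validated.
#'
#' @param path JSON file path, or a JSON string.
#' @return a `dn_model` (additionally `dn_cox` for Cox models).
#' @export
import_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$format, "dynogram-model"))
    stop("not a dynogram model file", call. = FALSE)
  columns <- unlist(obj$columns)
  beta <- as.numeric(unlist(obj$beta))
  p <- length(beta)
  if (length(columns) != p)
    stop("dimension mismatch: ", length(columns), " columns vs ", p,
         " coefficients", call. = FALSE)
  sigma <- do.call(rbind, lapply(obj$sigma, function(r) as.numeric(unlist(r))))
  if (!is.matrix(sigma) || nrow(sigma) != p || ncol(sigma) != p)
    stop("dimension mismatch: sigma must be ", p, " x ", p, call. = FALSE)
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma))))
    stop("sigma is not symmetric", call. = FALSE)

  terms <- lapply(obj$terms, term_from_list)
  specs <- lapply(obj$variable_specs, spec_from_list)
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  level_order <- lapply(obj$level_order %||% list(), unlist)
  formula <- if (obj$family == "cox")
    model_spec(family = "cox", terms = terms, time = obj$time,
               status = obj$status, level_order = level_order)
  else
    model_spec(response = obj$response, family = obj$family, link = obj$link,
               terms = terms, level_order = level_order)
  # freeze imported knots back into the formula's terms
  formula$terms <- terms

  out <- list(formula = formula, beta = stats::setNames(beta, columns),
              sigma = sigma, dispersion = obj$dispersion %||% NA_real_,
              df_residual = obj$df_residual, n_used = obj$n_used,
              n_dropped = obj$n_dropped %||% 0L, loglik = obj$loglik %||% NA_real_,
              family = obj$family, link = obj$link,
              column_labels = columns, terms = terms,
              has_intercept = isTRUE(obj$has_intercept),
              variable_specs = specs)
  dimnames(out$sigma) <- list(columns, columns)
  # recompute the column-to-term map from the terms and specs
  tc <- term_column_map(terms, specs, out$has_intercept)
  out$term_columns <- tc$term_columns
  out$column_term <- tc$column_term
  class(out) <- "dn_model"
  if (obj$family == "cox") {
    bl <- obj$cox$baseline
    s1 <- do.call(rbind, lapply(bl$s1, function(r) as.numeric(unlist(r))))
    out$baseline <- data.frame(time = unlist(bl$time),
                               n_event = unlist(bl$n_event),
                               n_risk = unlist(bl$n_risk),
                               s0 = unlist(bl$s0),
                               cumhaz = unlist(bl$cumhaz),
                               s1 = I(s1))
    out$ties <- obj$cox$ties
    out$covariate_means <- stats::setNames(as.numeric(unlist(obj$cox$covariate_means)),
                                           columns)
    out$n_events <- obj$cox$n_events
    out$max_follow_up <- obj$cox$max_follow_up
    class(out) <- c("dn_cox", class(out))
  }
  out
}

# number of design columns each term contributes, given frozen specs
term_width <- function(t, specs) {
  switch(t$kind,
         covariate = 1L,
         factor = length(specs[[t$vars]]$levels) - 1L,
         spline = t$k - 1L,
         interaction = prod(vapply(t$vars, function(v) {
           s <- specs[[v]]
           if (s$role == "factor") length(s$levels) - 1L
           else {
             # a spline constituent contributes its basis width
             1L
           }
         }, integer(1))))
}

term_column_map <- function(terms, specs, has_intercept) {
  # widths must account for spline constituents inside interactions
  spline_k <- list()
  for (t in terms) if (t$kind == "spline") spline_k[[t$vars]] <- t$k
  width <- vapply(terms, function(t) {
    if (t$kind == "interaction") {
      prod(vapply(t$vars, function(v) {
        s <- specs[[v]]
        if (s$role == "factor") length(s$levels) - 1L
        else if (!is.null(spline_k[[v]])) spline_k[[v]] - 1L
        else 1L
      }, integer(1)))
    } else term_width(t, specs)
  }, integer(1))
  column_term <- if (has_intercept) 0L else integer(0)
  term_columns <- vector("list", length(terms))
  at <- if (has_intercept) 1L else 0L
  for (i in seq_along(terms)) {
    term_columns[[i]] <- seq(at + 1L, length.out = width[i])
    at <- at + width[i]
    column_term <- c(column_term, rep(i, width[i]))
  }
  list(term_columns = term_columns, column_term = column_term)
}
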