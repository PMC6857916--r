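#' Model terms
#'
#' Terms are the building blocks of a model specification: plain covariates,
#' factors (treatment contrasts against the first level), restricted cubic
#' splines, and interactions of up to three variables whose main effects are
#' also in the model.
#'
#' @param var variable name.
#' @param k number of spline knots (3 to 7); ignored when `knots` is given.
#' @param knots optional explicit, strictly increasing knot vector.
#' @param vars character vector of 2 or 3 variable names to interact.
#' @return an object of class `dn_term`.
#' @name terms
NULL

new_term <- function(kind, vars, k = NULL, knots = NULL) {
  structure(list(kind = kind, vars = vars, k = k, knots = knots,
                 order = length(vars)),
            class = "dn_term")
}

#' @rdname terms
#' @export
term_covariate <- function(var) new_term("covariate", var)

#' @rdname terms
#' @export
term_factor <- function(var) new_term("factor", var)

#' @rdname terms
#' @export
term_spline <- function(var, k = 5, knots = NULL) {
  if (!is.null(knots)) {
    check_knots(knots)
    k <- length(knots)
  }
  if (!(k %in% 3:7)) stop("spline knot count k must be in 3..7", call. = FALSE)
  new_term("spline", var, k = as.integer(k), knots = knots)
}

#' @rdname terms
#' @export
term_interaction <- function(vars) {
  if (length(vars) < 2L || length(vars) > 3L)
    stop("interactions must involve 2 or 3 variables", call. = FALSE)
  if (anyDuplicated(vars)) stop("interaction repeats a variable", call. = FALSE)
  new_term("interaction", vars)
}

term_label <- function(term) {
  switch(term$kind,
         covariate = term$vars,
         factor = term$vars,
         spline = sprintf("rcs(%s, %d)", term$vars, term$k),
         interaction = paste(term$vars, collapse = ":"))
}

#' Specify a model
#'
#' Collects the response, the family/link pair and the ordered term list into
#' a model specification. Supported families are the generalised linear model
#' families with their canonical links (gaussian/identity, binomial/logit,
#' poisson/log, gamma/reciprocal) plus the Cox proportional hazards model,
#' which uses `time` and `status` variables instead of a response column.
#'
#' @param response response column name (ignored for `family = "cox"`).
#' @param family one of `"gaussian"`, `"binomial"`, `"poisson"`, `"gamma"`,
#'   `"cox"`.
#' @param link link name; defaults to the family's canonical link.
#' @param terms list of [term_covariate()], [term_factor()], [term_spline()],
#'   [term_interaction()] objects, in display order.
#' @param time,status event-time and 0/1 event-status column names (Cox only).
#' @param level_order optional named list giving an explicit level ordering
#'   for factors (first level = reference); the default is the lexicographic
#'   sort of observed labels.
#' @return an object of class `dn_formula`.
#' @export
model_spec <- function(response = NULL, family, link = NULL, terms,
                       time = NULL, status = NULL, level_order = list()) {
  family <- match.arg(family, c("gaussian", "binomial", "poisson", "gamma", "cox"))
  canonical <- c(gaussian = "identity", binomial = "logit",
                 poisson = "log", gamma = "inverse")
  if (family == "cox") {
    if (is.null(time) || is.null(status))
      stop("cox models need 'time' and 'status' variable names", call. = FALSE)
    if (!is.null(link)) stop("cox models do not take a link", call. = FALSE)
  } else {
    link <- link %||% unname(canonical[family])
    if (!identical(link, unname(canonical[family])))
      stop("unsupported family/link pair: ", family, "/", link, call. = FALSE)
    if (is.null(response)) stop("response is required", call. = FALSE)
  }
  if (!length(terms)) stop("at least one term is required", call. = FALSE)
  if (!all(vapply(terms, inherits, logical(1), "dn_term")))
    stop("terms must be dn_term objects", call. = FALSE)
  main_vars <- unlist(lapply(terms, function(t)
    if (t$kind != "interaction") t$vars else NULL))
  if (anyDuplicated(main_vars))
    stop("a variable appears in more than one main-effect term", call. = FALSE)
  for (t in terms) {
    if (t$kind == "interaction" && !all(t$vars %in% main_vars))
      stop("interaction ", term_label(t),
           ": every constituent needs a main-effect term", call. = FALSE)
  }
  structure(list(response = response, family = family, link = link,
                 terms = terms, time = time, status = status,
                 level_order = level_order),
            class = "dn_formula")
}

formula_vars <- function(formula) {
  unique(unlist(lapply(formula$terms, `[[`, "vars")))
}

#' @export
print.dn_formula <- function(x, ...) {
  lhs <- if (x$family == "cox")
    sprintf("Surv(%s, %s)", x$time, x$status) else x$response
  rhs <- paste(vapply(x$terms, term_label, character(1)), collapse = " + ")
  fam <- if (x$family == "cox") "cox" else paste0(x$family, "(", x$link, ")")
  cat(sprintf("<model spec> %s ~ %s  [%s]\n", lhs, rhs, fam))
  invisible(x)
}

#' Encode a factor as treatment-contrast indicators
#'
#' Produces `length(levels) - 1` binary indicator columns against the spec's
#' first (reference) level, labelled `"var(level)"`.
#'
#' @param values character vector of observed labels.
#' @param spec a factor [variable_spec()].
#' @return numeric matrix with one column per non-reference level.
#' @export
encode_factor <- function(values, spec) {
  stopifnot(inherits(spec, "dn_variable"), spec$role == "factor")
  values <- as.character(values)
  bad <- setdiff(unique(values), spec$levels)
  if (length(bad))
    stop("unseen level(s) for factor '", spec$name, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  non_ref <- spec$levels[-1L]
  m <- vapply(non_ref, function(l) as.numeric(values == l),
              numeric(length(values)))
  m <- matrix(m, nrow = length(values), ncol = length(non_ref))
  colnames(m) <- sprintf("%s(%s)", spec$name, non_ref)
  m
}

# Harrell's default knot-placement probabilities, indexed by knot count
knot_probs <- list(
  `3` = c(0.10, 0.50, 0.90),
  `4` = c(0.05, 0.35, 0.65, 0.95),
  `5` = c(0.05, 0.275, 0.50, 0.725, 0.95),
  `6` = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95),
  `7` = c(0.025, 0.1833, 0.3417, 0.50, 0.6583, 0.8167, 0.975))

#' Default quantile knots for a restricted cubic spline
#'
#' Places `k` knots at the empirical quantiles conventionally used for
#' restricted cubic splines (for `k = 5`: probabilities 0.05, 0.275, 0.5,
#' 0.725, 0.95).
#'
#' @param x numeric vector.
#' @param k knot count, 3 to 7.
#' @return strictly increasing numeric vector of length `k`.
#' @export
default_knots <- function(x, k = 5) {
  if (!(k %in% 3:7)) stop("k must be in 3..7", call. = FALSE)
  x <- x[is.finite(x)]
  if (length(unique(x)) < k)
    stop("need at least ", k, " distinct values to place ", k, " knots",
         call. = FALSE)
  kn <- unname(stats::quantile(x, probs = knot_probs[[as.character(k)]]))
  check_knots(kn)
  kn
}

check_knots <- function(knots) {
  if (length(knots) < 3L || any(diff(knots) <= 0))
    stop("knots must be strictly increasing with length >= 3", call. = FALSE)
  invisible(knots)
}

#' Restricted cubic spline basis
#'
#' Evaluates the restricted ("natural") cubic spline basis of Harrell's
#' truncated-power parametrization: column 1 is `x` itself and columns
#' `2..k-1` are cubic terms constrained so the fitted curve is linear beyond
#' the boundary knots, normalized by the squared boundary-knot span
#' `(t_k - t_1)^2` so all columns share the scale of `x`.
#'
#' @param x numeric vector of evaluation points.
#' @param knots strictly increasing knot vector, length `k >= 3`.
#' @return numeric matrix with `k - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  check_knots(knots)
  k <- length(knots)
  t1 <- knots[1L]; tk1 <- knots[k - 1L]; tk <- knots[k]
  norm <- (tk - t1)^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, nrow = length(x), ncol = k - 1L)
  out[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    out[, j + 1L] <- (pos3(x - tj) -
                        pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                        pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }
  out
}

spline_labels <- function(var, k) {
  c(var, paste0(var, vapply(seq_len(k - 2L), function(i)
    paste(rep("'", i), collapse = ""), character(1))))
}

# columns contributed by one main-effect term for given rows
term_block <- function(term, data, specs) {
  v <- term$vars
  switch(term$kind,
         covariate = {
           m <- matrix(as.numeric(data[[v]]), ncol = 1L)
           colnames(m) <- v
           m
         },
         factor = encode_factor(data[[v]], specs[[v]]),
         spline = {
           m <- rcs_basis(as.numeric(data[[v]]), term$knots)
           colnames(m) <- spline_labels(v, term$k)
           m
         },
         stop("term_block does not handle interactions directly"))
}

# elementwise products of the constituent main-effect blocks
interaction_block <- function(term, blocks) {
  parts <- blocks[term$vars]
  out <- parts[[1L]]
  for (p in parts[-1L]) {
    new <- matrix(0, nrow = nrow(out), ncol = ncol(out) * ncol(p))
    labs <- character(ncol(out) * ncol(p))
    idx <- 0L
    for (i in seq_len(ncol(out))) for (j in seq_len(ncol(p))) {
      idx <- idx + 1L
      new[, idx] <- out[, i] * p[, j]
      labs[idx] <- paste(colnames(out)[i], colnames(p)[j], sep = ":")
    }
    colnames(new) <- labs
    out <- new
  }
  out
}

#' Build the design matrix
#'
#' Translates a model specification plus raw data into a numeric design
#' matrix with full column-to-term metadata. Rows with a missing value in any
#' model variable are dropped (complete-case) and the dropped count recorded.
#' The intercept column comes first (except for Cox models, which have none);
#' interaction columns are elementwise products of the constituent
#' main-effect columns. Spline knots and factor level sets are frozen into
#' the returned object so new observations are encoded identically.
#'
#' @param data a data frame containing every model variable.
#' @param formula a [model_spec()].
#' @param variable_specs optional pre-frozen specs (used when encoding new
#'   data against an existing fit); when `NULL` they are computed from `data`.
#' @return an object of class `dn_design` with elements `X`,
#'   `column_labels`, `terms`, `term_columns`, `column_term`,
#'   `has_intercept`, `n_dropped`, `variable_specs`, `y`/`time`/`status`.
#' @export
build_design <- function(data, formula, variable_specs = NULL) {
  stopifnot(inherits(formula, "dn_formula"), is.data.frame(data))
  vars <- formula_vars(formula)
  extra <- if (formula$family == "cox") c(formula$time, formula$status)
           else formula$response
  need <- c(vars, extra)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("data lacks model variable(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  training <- is.null(variable_specs)
  keep <- stats::complete.cases(data[need])
  n_dropped <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  if (nrow(data) == 0L) stop("no usable rows after complete-case filtering",
                             call. = FALSE)
  if (n_dropped > 0L && training)
    message(n_dropped, " row(s) dropped due to missing values")

  roles <- list()
  for (t in formula$terms) {
    if (t$kind == "factor") roles[[t$vars]] <- "factor"
    else if (t$kind != "interaction") roles[[t$vars]] <- "covariate"
  }
  if (training) {
    variable_specs <- specs_from_data(data, vars, roles, formula$level_order)
    # freeze default knots from the observed covariate
    formula$terms <- lapply(formula$terms, function(t) {
      if (t$kind == "spline" && is.null(t$knots))
        t$knots <- default_knots(as.numeric(data[[t$vars]]), t$k)
      t
    })
  }

  has_intercept <- formula$family != "cox"
  enc <- encode_matrix(data, formula$terms, variable_specs, has_intercept)
  X <- enc$X

  if (training) {
    const <- apply(X, 2L, function(col) max(col) == min(col))
    if (has_intercept) const[1L] <- FALSE
    if (any(const))
      stop("constant non-intercept column(s) in design: ",
           paste(colnames(X)[const], collapse = ", "), call. = FALSE)
  }

  out <- list(X = X, column_labels = colnames(X), formula = formula,
              terms = formula$terms, term_columns = enc$term_columns,
              column_term = enc$column_term, has_intercept = has_intercept,
              n_dropped = n_dropped, variable_specs = variable_specs)
  if (formula$family == "cox") {
    out$time <- as.numeric(data[[formula$time]])
    out$status <- as.numeric(data[[formula$status]])
  } else {
    out$y <- as.numeric(data[[formula$response]])
  }
  class(out) <- "dn_design"
  out
}

# assemble intercept + per-term blocks into one matrix with term metadata
encode_matrix <- function(data, terms, variable_specs, has_intercept) {
  blocks <- list()
  for (t in terms)
    if (t$kind != "interaction")
      blocks[[t$vars]] <- term_block(t, data, variable_specs)

  cols <- if (has_intercept) {
    m <- matrix(1, nrow(data), 1L); colnames(m) <- "(Intercept)"; list(m)
  } else list()
  column_term <- if (has_intercept) 0L else integer(0)
  term_columns <- vector("list", length(terms))
  for (i in seq_along(terms)) {
    t <- terms[[i]]
    b <- if (t$kind == "interaction") interaction_block(t, blocks)
         else blocks[[t$vars]]
    first <- sum(vapply(cols, ncol, integer(1))) + 1L
    term_columns[[i]] <- seq(first, length.out = ncol(b))
    column_term <- c(column_term, rep(i, ncol(b)))
    cols <- c(cols, list(b))
  }
  list(X = do.call(cbind, cols), column_term = column_term,
       term_columns = term_columns)
}

# encode new observations against a frozen fit: returns a matrix whose
# columns match the training design exactly
encode_rows <- function(formula, variable_specs, newdata, has_intercept = TRUE,
                        warn_extrapolation = TRUE) {
  vars <- formula_vars(formula)
  for (v in vars) {
    if (is.null(newdata[[v]]))
      stop("new observation lacks variable '", v, "'", call. = FALSE)
    sp <- variable_specs[[v]]
    if (sp$role == "covariate" && warn_extrapolation) {
      x <- as.numeric(newdata[[v]])
      if (any(x < sp$observed_min | x > sp$observed_max))
        warning("covariate '", v, "' outside the observed range [",
                format(sp$observed_min), ", ", format(sp$observed_max),
                "]; extrapolating", call. = FALSE)
    }
  }
  df <- as.data.frame(lapply(newdata[vars], function(x) x),
                      stringsAsFactors = FALSE, check.names = FALSE)
  encode_matrix(df, formula$terms, variable_specs, has_intercept)$X
}
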