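#' Input controls derived from a fitted model
#'
#' One control per model variable, in formula order: covariates become
#' sliders bounded by their observed ranges with the observed mean as the
#' default value and a step of roughly 1/100 of the range rounded to a
#' presentable increment; factors become drop-downs over their levels with
#' the observed mode as the default.
#'
#' @param model a fitted `dn_model`.
#' @return list of control specifications.
#' @export
control_spec <- function(model) {
  vars <- formula_vars(model$formula)
  lapply(vars, function(v) {
    s <- model$variable_specs[[v]]
    if (s$role == "factor")
      list(variable = v, widget = "dropdown", options = s$levels,
           default = s$mode)
    else
      list(variable = v, widget = "slider", min = s$observed_min,
           max = s$observed_max,
           step = nice_step((s$observed_max - s$observed_min) / 100),
           default = s$mean)
  })
}

#' Start an interactive scenario session
#'
#' A session accumulates user scenarios: each added scenario is evaluated
#' through the prediction layer (point estimate and interval on the response
#' scale, or a survival curve for Cox models) and kept in order. Duplicate
#' inputs are appended, not merged. The session is a plain value: adding a
#' scenario returns a new session.
#'
#' @param model a fitted `dn_model`.
#' @param level confidence level used for every scenario.
#' @return an object of class `dn_session`.
#' @export
nomogram_session <- function(model, level = 0.95) {
  stopifnot(inherits(model, "dn_model"), level > 0, level < 1)
  structure(list(model = model, level = level, scenarios = list()),
            class = "dn_session")
}

#' Add a scenario to a session
#'
#' @param session a [nomogram_session()].
#' @param inputs named list of input values for every model variable.
#' @return the updated session; on invalid input an error is thrown and the
#'   session is unchanged.
#' @export
add_scenario <- function(session, inputs) {
  stopifnot(inherits(session, "dn_session"))
  model <- session$model
  result <- if (inherits(model, "dn_cox")) {
    curve <- survival_curve(model, inputs)
    curve$alpha <- pmax(0.1, curve$at_risk_fraction)
    curve
  } else {
    predict_response(model, inputs, level = session$level)
  }
  session$scenarios[[length(session$scenarios) + 1L]] <-
    list(inputs = as.list(inputs), result = result)
  session
}

#' Numerical summary of all scenarios
#'
#' One row per scenario: every input value/level followed by the estimate and
#' interval on the response scale. For Cox sessions the summary reports
#' predicted survival at `at_time` (default: the median observed event time).
#'
#' @param session a [nomogram_session()].
#' @param digits formatting precision (applied to the numeric columns).
#' @param at_time time point for Cox survival summaries.
#' @return a data frame (empty, with the right columns, for an empty session).
#' @export
numerical_summary <- function(session, digits = 3, at_time = NULL) {
  stopifnot(inherits(session, "dn_session"))
  model <- session$model
  vars <- formula_vars(model$formula)
  is_cox <- inherits(model, "dn_cox")
  if (is_cox && is.null(at_time))
    at_time <- stats::median(model$baseline$time)
  rows <- lapply(session$scenarios, function(sc) {
    vals <- lapply(vars, function(v) {
      x <- sc$inputs[[v]]
      if (is.numeric(x)) round(x, digits) else as.character(x)
    })
    names(vals) <- vars
    if (is_cox) {
      s <- survival_at(model, sc$inputs, at_time, level = session$level)
      c(vals, list(time = at_time, estimate = round(s$estimate, digits),
                   lower = round(s$lower, digits),
                   upper = round(s$upper, digits)))
    } else {
      r <- sc$result
      c(vals, list(estimate = round(r$response_estimate, digits),
                   lower = round(r$response_lower, digits),
                   upper = round(r$response_upper, digits)))
    }
  })
  if (!length(rows)) {
    cols <- c(vars, if (is_cox) "time", "estimate", "lower", "upper")
    df <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)),
                                        cols))
    return(df)
  }
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
}

#' Formatted coefficient summary
#'
#' Coefficient, standard error, Wald statistic and p-value per design column;
#' z statistics for fixed-dispersion families (binomial, Poisson, Cox) and t
#' statistics when the dispersion is estimated (gaussian, gamma). Cox
#' summaries add hazard ratios with confidence intervals.
#'
#' @param model a fitted `dn_model`.
#' @param level confidence level for Cox hazard-ratio intervals.
#' @return a data frame of class `dn_summary` with family/link/n attributes.
#' @export
model_summary <- function(model, level = 0.95) {
  se <- sqrt(diag(model$sigma))
  stat <- model$beta / se
  t_based <- model$family %in% c("gaussian", "gamma")
  pval <- if (t_based) 2 * stats::pt(-abs(stat), df = model$df_residual)
          else 2 * stats::pnorm(-abs(stat))
  out <- data.frame(term = model$column_labels,
                    estimate = as.numeric(model$beta), std_error = se,
                    statistic = as.numeric(stat), p_value = as.numeric(pval),
                    stringsAsFactors = FALSE)
  names(out)[4] <- if (t_based) "t_value" else "z_value"
  if (inherits(model, "dn_cox")) {
    q <- stats::qnorm(1 - (1 - level) / 2)
    out$hazard_ratio <- exp(out$estimate)
    out$hr_lower <- exp(out$estimate - q * se)
    out$hr_upper <- exp(out$estimate + q * se)
  }
  rownames(out) <- NULL
  structure(out, class = c("dn_summary", "data.frame"),
            family = model$family, link = model$link, n = model$n_used,
            loglik = model$loglik)
}

#' @export
print.dn_summary <- function(x, digits = 4, ...) {
  fam <- attr(x, "family")
  cat(sprintf("Family: %s%s   n = %d   loglik = %.2f\n", fam,
              if (!is.null(attr(x, "link")) && fam != "cox")
                paste0(" (", attr(x, "link"), ")") else "",
              attr(x, "n"), attr(x, "loglik")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(c) signif(c, digits))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' View-model for a UI host
#'
#' Serialises the session into the JSON-ready structure a front end renders:
#' the control definitions, one plot element per scenario (point + interval,
#' or a step survival curve with per-segment alpha values reflecting the
#' at-risk fraction, floored at 0.1), and the numerical summary table. Every
#' number is produced by the prediction layer; the view-model adds no
#' statistics of its own.
#'
#' @param session a [nomogram_session()].
#' @param digits numeric formatting for the summary table.
#' @return a plain list.
#' @export
view_model <- function(session, digits = 3) {
  model <- session$model
  is_cox <- inherits(model, "dn_cox")
  scen <- lapply(seq_along(session$scenarios), function(i) {
    sc <- session$scenarios[[i]]
    if (is_cox) {
      r <- sc$result
      list(id = i, inputs = sc$inputs, type = "survival_curve",
           times = r$times, survival = r$survival, alpha = r$alpha)
    } else {
      r <- sc$result
      list(id = i, inputs = sc$inputs, type = "point_interval",
           estimate = r$response_estimate, lower = r$response_lower,
           upper = r$response_upper, level = r$level)
    }
  })
  list(model = list(family = model$family, link = model$link,
                    n = model$n_used),
       controls = control_spec(model),
       level = session$level,
       scenarios = scen,
       numerical_summary = numerical_summary(session, digits = digits),
       model_summary = as.data.frame(model_summary(model)))
}

#' Export a deployable prediction bundle
#'
#' Writes a directory containing the serialized model, the app configuration
#' (confidence level and input controls), a runnable entry script and a
#' manifest with checksums. The bundle is hermetic: it carries everything
#' prediction needs and never references the training data.
#'
#' @param model a fitted `dn_model`.
#' @param outdir output directory (created if needed).
#' @param level default confidence level for the bundled app.
#' @param title app title.
#' @return character vector of the files written, invisibly.
#' @export
export_bundle <- function(model, outdir, level = 0.95, title = "dynogram app") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create '", outdir, "'", call. = FALSE)
  export_model(model, file.path(outdir, "model.json"))
  jsonlite::write_json(list(title = title, level = level,
                            controls = control_spec(model)),
                       file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  writeLines(bundle_app_script(), file.path(outdir, "app.R"))
  files <- c("model.json", "config.json", "app.R")
  md5 <- as.character(tools::md5sum(file.path(outdir, files)))
  jsonlite::write_json(list(format = "dynogram-bundle", version = 1L,
                            files = files,
                            md5 = as.list(stats::setNames(md5, files))),
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(file.path(outdir, c(files, "manifest.json")))
}

bundle_app_script <- function() {
  c('#!/usr/bin/env Rscript',
    '# Self-contained dynamic-nomogram app over the bundled model.',
    '#   Rscript app.R --at "age=40,pclass=1st,sex=male" [--level 0.95] [--time 250]',
    '# With no --at argument, starts a console session prompting for inputs.',
    'library(dynogram)',
    'here <- dirname(sub("^--file=", "", grep("^--file=", commandArgs(FALSE), value = TRUE)[1]))',
    'if (is.na(here) || !nzchar(here)) here <- "."',
    'model <- import_model(file.path(here, "model.json"))',
    'config <- jsonlite::fromJSON(file.path(here, "config.json"), simplifyVector = FALSE)',
    'args <- commandArgs(TRUE)',
    'getopt <- function(flag, default = NULL) {',
    '  i <- match(flag, args)',
    '  if (is.na(i) || i == length(args)) default else args[i + 1]',
    '}',
    'level <- as.numeric(getopt("--level", config$level))',
    'at <- getopt("--at")',
    'if (!is.null(at)) {',
    '  out <- serve_scenario(model, at, level = level,',
    '                        time = as.numeric(getopt("--time", NA)))',
    '  cat(out, "\\n")',
    '} else {',
    '  serve_session(model, level = level)',
    '}')
}

# parse "a=1,b=x" into a typed input list against the model specs
parse_scenario <- function(model, text) {
  parts <- strsplit(strsplit(text, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- list()
  for (p in parts) {
    if (length(p) != 2L) stop("cannot parse scenario fragment: ",
                              paste(p, collapse = "="), call. = FALSE)
    v <- trimws(p[1]); x <- trimws(p[2])
    s <- model$variable_specs[[v]]
    if (is.null(s)) stop("unknown variable '", v, "'", call. = FALSE)
    vals[[v]] <- if (s$role == "factor") x else as.numeric(x)
  }
  vals
}

#' Evaluate one scenario and return its JSON payload
#'
#' The unit of work the bundle entry script and the CLI share: parse a
#' `"var=value,..."` scenario string, run it through the prediction layer and
#' return the JSON the UI would display.
#'
#' @param model a fitted `dn_model`.
#' @param at scenario string, e.g. `"age=40,pclass=1st,sex=male"`.
#' @param level confidence level.
#' @param time optional time point (Cox models) for predicted survival.
#' @return JSON string.
#' @export
serve_scenario <- function(model, at, level = 0.95, time = NA) {
  inputs <- parse_scenario(model, at)
  out <- if (inherits(model, "dn_cox")) {
    curve <- survival_curve(model, inputs)
    res <- list(inputs = inputs, type = "survival_curve",
                times = curve$times, survival = curve$survival,
                alpha = pmax(0.1, curve$at_risk_fraction))
    if (!is.na(time))
      res$survival_at <- survival_at(model, inputs, time, level = level)
    res
  } else {
    p <- predict_response(model, inputs, level = level)
    list(inputs = inputs, type = "point_interval",
         estimate = p$response_estimate, lower = p$response_lower,
         upper = p$response_upper, level = level)
  }
  as.character(jsonlite::toJSON(out, auto_unbox = TRUE, digits = I(17)))
}

#' Minimal console host for a model
#'
#' A reference host for the view-model service contract: prompts for
#' scenarios on the console (format `var=value,...`), prints each
#' prediction's JSON payload, and keeps the running numerical summary.
#' Intended for interactive use; any richer UI should consume
#' [view_model()] / [serve_scenario()] instead.
#'
#' @param model a fitted `dn_model`.
#' @param level confidence level.
#' @return the final session, invisibly.
#' @export
serve_session <- function(model, level = 0.95) {
  session <- nomogram_session(model, level = level)
  cat("dynogram console session. Controls:\n")
  for (ctl in control_spec(model)) {
    if (ctl$widget == "slider")
      cat(sprintf("  %s: slider [%g, %g], default %g\n", ctl$variable,
                  ctl$min, ctl$max, ctl$default))
    else
      cat(sprintf("  %s: dropdown {%s}, default %s\n", ctl$variable,
                  paste(ctl$options, collapse = ", "), ctl$default))
  }
  cat("Enter scenarios as var=value,var=value (empty line to quit):\n")
  repeat {
    line <- if (interactive()) readline("> ") else readLines(n = 1)
    if (!length(line) || !nzchar(trimws(line))) break
    res <- tryCatch({
      session <<- add_scenario(session, parse_scenario(model, line))
      cat(serve_scenario(model, line, level = level), "\n")
      TRUE
    }, error = function(e) { cat("error:", conditionMessage(e), "\n"); FALSE })
  }
  if (length(session$scenarios)) print(numerical_summary(session))
  invisible(session)
}

#' Load a bundle's model
#'
#' Verifies the manifest checksums, then imports the bundled model.
#'
#' @param dir bundle directory written by [export_bundle()].
#' @return a `dn_model`.
#' @export
load_bundle <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                            simplifyVector = FALSE)
  if (!identical(man$format, "dynogram-bundle"))
    stop("not a dynogram bundle", call. = FALSE)
  for (f in man$files) {
    f <- as.character(f)
    got <- as.character(tools::md5sum(file.path(dir, f)))
    if (!identical(got, man$md5[[f]]))
      stop("checksum mismatch for bundle file '", f, "'", call. = FALSE)
  }
  import_model(file.path(dir, "model.json"))
}
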