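#' Linear predictor and its standard error for a new observation
#'
#' Encodes one new observation against the model's frozen variable
#' specifications and spline knots, then returns `eta = x* beta` and
#' `se_eta = sqrt(x* Sigma x*)`. For Cox models the row is centered at the
#' training covariate means, so `eta` is the centered linear predictor.
#' Covariates outside the observed range trigger an extrapolation warning,
#' not an error; unknown factor levels are errors.
#'
#' @param model a fitted `dn_model`.
#' @param x_new named list/vector mapping each model variable to a value
#'   (numeric for covariates, level label for factors).
#' @return list with `eta`, `se_eta` and the encoded row `x_row`.
#' @export
linear_predictor <- function(model, x_new) {
  x_row <- encode_rows(model$formula, model$variable_specs, as.list(x_new),
                       has_intercept = model$has_intercept)
  if (nrow(x_row) != 1L) stop("x_new must describe a single observation",
                              call. = FALSE)
  xv <- drop(x_row)
  if (inherits(model, "dn_cox")) xv <- xv - model$covariate_means
  eta <- sum(xv * model$beta)
  se_eta <- sqrt(max(0, drop(t(xv) %*% model$sigma %*% xv)))
  list(eta = eta, se_eta = se_eta, x_row = xv)
}

#' Confidence interval on the linear-predictor scale
#'
#' `eta +/- critical * se_eta`, where the critical value is a standard-normal
#' quantile for fixed-dispersion families (binomial, Poisson, Cox) and a
#' Student-t quantile on the residual degrees of freedom when the dispersion
#' is estimated (gaussian, gamma).
#'
#' @param eta,se_eta linear predictor and its standard error.
#' @param level confidence level in (0, 1).
#' @param model the fitted model (decides the reference distribution).
#' @return numeric vector `c(lower, upper)`.
#' @export
confidence_interval <- function(eta, se_eta, level = 0.95, model) {
  if (!(level >= 0 && level < 1)) stop("level must be in [0, 1)", call. = FALSE)
  q <- 1 - (1 - level) / 2
  crit <- if (model$family %in% c("gaussian", "gamma"))
    stats::qt(q, df = model$df_residual) else stats::qnorm(q)
  c(eta - crit * se_eta, eta + crit * se_eta)
}

#' Inverse link transform
#'
#' Maps linear-predictor values to the response scale: identity `eta`, logit
#' `exp(eta)/(1 + exp(eta))`, log `exp(eta)`, reciprocal `1/eta`.
#'
#' @param family model family (validates the pairing).
#' @param link link name.
#' @param eta numeric vector of linear-predictor values.
#' @return numeric vector on the response scale.
#' @export
inverse_link <- function(family, link, eta) {
  fam <- family_info(family, link)
  fam$linkinv(eta)
}

#' Response-scale prediction with confidence interval
#'
#' Composes [linear_predictor()], [confidence_interval()] and
#' [inverse_link()]: the interval is computed on the linear scale and the
#' inverse link applied to the estimate and both limits (limits swap when the
#' inverse link is decreasing, as for the reciprocal link). For the
#' reciprocal link an interval spanning zero has no defined mean response and
#' is an error.
#'
#' @param model a fitted (non-Cox) `dn_model`.
#' @param x_new named list of input values, as in [linear_predictor()].
#' @param level confidence level.
#' @return an object of class `dn_prediction` with `inputs`, `eta`, `se_eta`,
#'   `level`, `response_estimate`, `response_lower`, `response_upper`.
#' @export
predict_response <- function(model, x_new, level = 0.95) {
  if (inherits(model, "dn_cox"))
    stop("use survival_curve()/survival_at() for Cox models", call. = FALSE)
  lp <- linear_predictor(model, x_new)
  ci <- confidence_interval(lp$eta, lp$se_eta, level, model)
  fam <- family_info(model$family, model$link)
  if (model$link == "inverse" && ci[1] < 0 && ci[2] > 0)
    stop("reciprocal-link interval spans zero: mean response undefined",
         call. = FALSE)
  vals <- fam$linkinv(c(lp$eta, ci))
  lim <- sort(vals[2:3])
  structure(list(inputs = as.list(x_new), eta = lp$eta, se_eta = lp$se_eta,
                 level = level, response_estimate = vals[1],
                 response_lower = lim[1], response_upper = lim[2]),
            class = "dn_prediction")
}

#' @export
print.dn_prediction <- function(x, digits = 4, ...) {
  ins <- paste(names(x$inputs), vapply(x$inputs, format, character(1)),
               sep = "=", collapse = ", ")
  cat(sprintf("<prediction> %s\n  estimate %.*f  [%.*f, %.*f]  (%.0f%% CI)\n",
              ins, digits, x$response_estimate, digits, x$response_lower,
              digits, x$response_upper, 100 * x$level))
  invisible(x)
}

#' Predicted survival curve for a new observation
#'
#' `S(t | x) = exp(-Lambda0(t) * exp((x - xbar) beta))` as a right-continuous
#' step function over the distinct event times, together with the at-risk
#' fraction at each step (used for alpha-blending of the plotted curve).
#'
#' @param model a fitted `dn_cox` model.
#' @param x_new named list of covariate/factor values.
#' @return an object of class `dn_survcurve` with `times`, `survival`,
#'   `at_risk_fraction`, `inputs`, `eta`.
#' @export
survival_curve <- function(model, x_new) {
  stopifnot(inherits(model, "dn_cox"))
  lp <- linear_predictor(model, x_new)
  risk <- exp(lp$eta)
  base <- model$baseline
  structure(list(times = base$time,
                 survival = exp(-base$cumhaz * risk),
                 at_risk_fraction = base$n_risk / model$n_used,
                 inputs = as.list(x_new), eta = lp$eta, se_eta = lp$se_eta),
            class = "dn_survcurve")
}

#' Predicted survival at a time point, with confidence interval
#'
#' The point estimate is the survival-curve value at `t`; the interval is
#' computed on the log-cumulative-hazard scale by the delta method
#' (accounting for both the baseline-hazard variance and the coefficient
#' covariance), back-transformed and clamped to `[0, 1]`.
#'
#' @param model a fitted `dn_cox` model.
#' @param x_new named list of covariate/factor values.
#' @param t time point within the observed follow-up.
#' @param level confidence level.
#' @return list with `time`, `estimate`, `lower`, `upper`, `level`.
#' @export
survival_at <- function(model, x_new, t, level = 0.95) {
  stopifnot(inherits(model, "dn_cox"))
  if (t > model$max_follow_up)
    stop("t = ", t, " lies beyond the last observed follow-up time (",
         model$max_follow_up, ")", call. = FALSE)
  lp <- linear_predictor(model, x_new)
  risk <- exp(lp$eta)
  base <- model$baseline
  j <- base$time <= t
  if (!any(j)) {
    # before the first event: no cumulated hazard, degenerate certainty
    return(list(time = t, estimate = 1, lower = 1, upper = 1, level = level))
  }
  d <- base$n_event[j]; s0 <- base$s0[j]
  s1 <- matrix(base$s1[j, , drop = FALSE], nrow = sum(j))
  lambda0 <- sum(d / s0)
  Lambda <- lambda0 * risk
  # delta method: Var(Lambda-hat) = e^{2 eta} Var(Lambda0) + g' Sigma g,
  # g = d Lambda / d beta = e^{eta} (z* Lambda0 - sum d_j S1_j / S0_j^2)
  v_base <- risk^2 * sum(d / s0^2)
  g <- risk * (lp$x_row * lambda0 - colSums((d / s0^2) * s1))
  v <- v_base + drop(t(g) %*% model$sigma %*% g)
  se_log <- sqrt(v) / Lambda
  q <- stats::qnorm(1 - (1 - level) / 2)
  Lam_lo <- Lambda * exp(-q * se_log)
  Lam_hi <- Lambda * exp(q * se_log)
  est <- exp(-Lambda)
  lims <- sort(c(exp(-Lam_hi), exp(-Lam_lo)))
  list(time = t, estimate = min(max(est, 0), 1),
       lower = min(max(lims[1], 0), 1), upper = min(max(lims[2], 0), 1),
       level = level)
}
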