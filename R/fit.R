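# family/link machinery: canonical pairs only (identity, logit, log,
# reciprocal); each entry supplies the inverse link, d mu / d eta, the
# variance function and the support check for the response
family_info <- function(family, link) {
  switch(family,
    gaussian = list(
      linkfun = function(mu) mu, linkinv = function(eta) eta,
      mu_eta = function(eta) rep(1, length(eta)),
      variance = function(mu) rep(1, length(mu)),
      check_y = function(y) TRUE,
      decreasing = FALSE),
    binomial = list(
      linkfun = function(mu) log(mu / (1 - mu)),
      linkinv = function(eta) 1 / (1 + exp(-eta)),
      mu_eta = function(eta) { p <- 1 / (1 + exp(-eta)); p * (1 - p) },
      variance = function(mu) mu * (1 - mu),
      check_y = function(y) all(y %in% c(0, 1)),
      decreasing = FALSE),
    poisson = list(
      linkfun = log, linkinv = exp, mu_eta = exp,
      variance = function(mu) mu,
      check_y = function(y) all(y >= 0 & y == round(y)),
      decreasing = FALSE),
    gamma = list(
      linkfun = function(mu) 1 / mu, linkinv = function(eta) 1 / eta,
      mu_eta = function(eta) -1 / eta^2,
      variance = function(mu) mu^2,
      check_y = function(y) all(y > 0),
      decreasing = TRUE),
    stop("unsupported family: ", family, call. = FALSE))
}

new_model <- function(design, beta, sigma, dispersion, df_residual, loglik,
                      extra = list()) {
  stopifnot(length(beta) == ncol(design$X))
  out <- c(list(
    formula = design$formula, beta = stats::setNames(beta, design$column_labels),
    sigma = sigma, dispersion = dispersion, df_residual = df_residual,
    n_used = nrow(design$X), n_dropped = design$n_dropped, loglik = loglik,
    family = design$formula$family, link = design$formula$link,
    column_labels = design$column_labels, terms = design$terms,
    term_columns = design$term_columns, has_intercept = design$has_intercept,
    variable_specs = design$variable_specs), extra)
  dimnames(out$sigma) <- list(design$column_labels, design$column_labels)
  class(out) <- "dn_model"
  out
}

#' Ordinary least squares
#'
#' Closed-form least-squares fit via the QR decomposition, with the residual
#' mean square as the dispersion estimate and
#' `sigma = dispersion * (X'X)^-1` as the coefficient covariance.
#'
#' @param design a [build_design()] result.
#' @param y numeric response vector; defaults to the response stored in the
#'   design.
#' @return a fitted model of class `dn_model`.
#' @export
fit_ols <- function(design, y = design$y) {
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more rows than columns (n > p)", call. = FALSE)
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    bad <- design$column_labels[qr_x$pivot[(qr_x$rank + 1L):p]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_x, y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  dispersion <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(qr_x))
  sigma2_ml <- rss / n
  loglik <- -n / 2 * (log(2 * pi * sigma2_ml) + 1)
  new_model(design, beta, dispersion * xtx_inv, dispersion, n - p, loglik,
            extra = list(rss = rss, fitted = drop(X %*% beta)))
}

#' Generalised linear model fit by IRLS
#'
#' Iteratively reweighted least squares for the canonical-link families. The
#' dispersion is fixed at 1 for binomial and Poisson models and estimated by
#' the Pearson statistic for gamma models; the coefficient covariance is
#' `dispersion * (X'WX)^-1` at the final weights. Starting values are zero
#' with the intercept at the link of the mean response.
#'
#' @param design a [build_design()] result.
#' @param y response vector (0/1 for binomial, non-negative integers for
#'   Poisson, positive for gamma).
#' @param family,link family and link; default from the design's formula.
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   change.
#' @param max_iter iteration cap.
#' @return a fitted model of class `dn_model`.
#' @export
fit_glm_irls <- function(design, y = design$y, family = design$formula$family,
                         link = design$formula$link, tol = 1e-9,
                         max_iter = 50L) {
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  fam <- family_info(family, link)
  if (!fam$check_y(y))
    stop("response outside the support of the ", family, " family",
         call. = FALSE)

  # mu-based start (as in standard IRLS): initialize at the adjusted
  # observations, which keeps the reciprocal link away from its pole
  mu <- switch(family,
               gaussian = y,
               binomial = (y + 0.5) / 2,
               poisson = y + 0.1,
               gamma = pmax(y, mean(y) / 100))
  eta <- fam$linkfun(mu)
  beta <- rep(NA_real_, p)
  trace <- numeric(0)
  w <- NULL
  for (iter in seq_len(max_iter)) {
    dmu <- fam$mu_eta(eta)
    v <- fam$variance(mu)
    if (any(!is.finite(mu)) || any(v <= 0) || any(dmu == 0))
      stop("IRLS produced invalid fitted values at iteration ", iter,
           " (possible separation or divergence)", call. = FALSE)
    w <- dmu^2 / v
    z <- eta + (y - mu) / dmu
    sw <- sqrt(w)
    fit <- qr(X * sw)
    if (fit$rank < p) {
      bad <- design$column_labels[fit$pivot[(fit$rank + 1L):p]]
      stop("design is rank deficient; collinear column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    beta_new <- qr.coef(fit, z * sw)
    delta <- if (anyNA(beta)) Inf else max(abs(beta_new - beta))
    trace <- c(trace, delta)
    beta <- beta_new
    eta <- drop(X %*% beta)
    mu <- fam$linkinv(eta)
    if (any(!is.finite(mu)))
      stop("IRLS produced invalid fitted values at iteration ", iter,
           " (possible separation or divergence)", call. = FALSE)
    if (max(abs(beta)) > 1e4)
      stop("coefficients diverging (|beta| > 1e4): separation suspected",
           call. = FALSE)
    if (delta < tol) break
    if (iter == max_iter)
      stop("IRLS failed to converge in ", max_iter,
           " iterations; coefficient-change trace: ",
           paste(signif(utils::tail(trace, 5), 3), collapse = ", "),
           call. = FALSE)
  }
  w <- fam$mu_eta(eta)^2 / fam$variance(mu)
  xtwx_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
  pearson <- sum((y - mu)^2 / fam$variance(mu))
  dispersion <- switch(family,
                       gaussian = sum((y - mu)^2) / (n - p),
                       gamma = pearson / (n - p),
                       1)
  loglik <- switch(family,
    gaussian = { s2 <- sum((y - mu)^2) / n
                 -n / 2 * (log(2 * pi * s2) + 1) },
    binomial = sum(stats::dbinom(y, 1, mu, log = TRUE)),
    poisson = sum(stats::dpois(y, mu, log = TRUE)),
    gamma = { shape <- 1 / dispersion
              sum(stats::dgamma(y, shape = shape, rate = shape / mu, log = TRUE)) })
  new_model(design, beta, dispersion * xtwx_inv, dispersion, n - p, loglik,
            extra = list(iterations = iter, fitted = mu,
                         pearson = pearson))
}

#' Fit a model specification to data
#'
#' Convenience wrapper: builds the design matrix then dispatches to
#' [fit_ols()] (gaussian/identity), [fit_glm_irls()] (other GLM families) or
#' [fit_cox()] (Cox proportional hazards).
#'
#' @param data a data frame.
#' @param formula a [model_spec()].
#' @param ... passed to the underlying fitter.
#' @return a fitted model of class `dn_model` (additionally `dn_cox` for Cox
#'   models).
#' @export
fit_model <- function(data, formula, ...) {
  design <- build_design(data, formula)
  switch(formula$family,
         gaussian = fit_ols(design, ...),
         cox = fit_cox(design, ...),
         fit_glm_irls(design, ...))
}

#' @export
print.dn_model <- function(x, ...) {
  fam <- if (x$family == "cox") "cox" else paste0(x$family, "(", x$link, ")")
  cat(sprintf("<dynogram model> %s, n = %d (%d dropped), loglik = %.3f\n",
              fam, x$n_used, x$n_dropped, x$loglik))
  print(model_summary(x), ...)
  invisible(x)
}
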