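#' Specify a synthetic dataset
#'
#' Describes a data-generating process for any supported model family:
#' covariate distributions, factor level probabilities, the generating
#' coefficient for every design column, and for Cox models a constant
#' baseline hazard rate with uniform censoring. Together with the seed this
#' fully determines the generated bundle, so every test input is
#' reproducible and carries its own truth.
#'
#' @param family one of `"gaussian"`, `"binomial"`, `"poisson"`, `"gamma"`,
#'   `"cox"`.
#' @param n number of rows.
#' @param beta named numeric vector of generating coefficients: for GLM
#'   families the first element is the intercept, then one per design column
#'   in term order; for Cox no intercept.
#' @param covariates named list: `list(x = list(dist = "normal", mean = 0,
#'   sd = 1))` or `list(dist = "uniform", min = a, max = b)`.
#' @param factors named list: `list(f = list(levels = c("a","b"),
#'   probs = c(.5,.5)))`.
#' @param seed integer RNG seed, recorded in the bundle.
#' @param sd gaussian residual standard deviation.
#' @param shape gamma shape parameter.
#' @param baseline_rate constant baseline hazard rate (Cox).
#' @param censor_max upper end of the uniform censoring window (Cox).
#' @return an object of class `dn_synthspec`.
#' @export
synthetic_spec <- function(family, n, beta, covariates = list(),
                           factors = list(), seed = 1L, sd = 1, shape = 2,
                           baseline_rate = 0.1, censor_max = NULL) {
  family <- match.arg(family, c("gaussian", "binomial", "poisson", "gamma", "cox"))
  stopifnot(n > 0, length(covariates) + length(factors) > 0)
  structure(list(family = family, n = as.integer(n), beta = beta,
                 covariates = covariates, factors = factors,
                 seed = as.integer(seed), sd = sd, shape = shape,
                 baseline_rate = baseline_rate, censor_max = censor_max),
            class = "dn_synthspec")
}

draw_covariate <- function(cfg, n) {
  dist <- cfg$dist %||% "normal"
  switch(dist,
         normal = stats::rnorm(n, cfg$mean %||% 0, cfg$sd %||% 1),
         uniform = stats::runif(n, cfg$min %||% 0, cfg$max %||% 1),
         stop("unsupported covariate distribution: ", dist, call. = FALSE))
}

#' Generate a synthetic dataset bundle
#'
#' Draws covariates and factors per the spec, forms the linear predictor
#' `eta = X beta`, and draws the response from the family: gaussian
#' `N(eta, sd^2)`, bernoulli with `plogis(eta)`, Poisson with `exp(eta)`,
#' gamma with the stated shape and mean `1/eta`, and for Cox exponential
#' event times with hazard `baseline_rate * exp(eta)` under uniform
#' censoring. The generating parameters (including the seed) are stored in
#' the bundle, and the caller's RNG state is left untouched.
#'
#' @param spec a [synthetic_spec()].
#' @return a `dn_bundle` with `provenance = "synthetic"`, carrying a ready
#'   [model_spec()] in `$formula` and the generating parameters in
#'   `$params`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "dn_synthspec"))
  with_seed(spec$seed, {
    n <- spec$n
    d <- list()
    terms <- list()
    for (v in names(spec$covariates)) {
      d[[v]] <- draw_covariate(spec$covariates[[v]], n)
      terms[[length(terms) + 1L]] <- term_covariate(v)
    }
    for (v in names(spec$factors)) {
      cfg <- spec$factors[[v]]
      d[[v]] <- sample(cfg$levels, n, replace = TRUE,
                       prob = cfg$probs %||% NULL)
      terms[[length(terms) + 1L]] <- term_factor(v)
    }
    d <- as.data.frame(d, stringsAsFactors = FALSE)

    formula <- if (spec$family == "cox")
      model_spec(family = "cox", terms = terms, time = "time",
                 status = "status")
    else
      model_spec(response = "y", family = spec$family, terms = terms)

    # encode against the drawn data to get the design implied by the spec
    specs <- specs_from_data(d, names(d),
                             stats::setNames(as.list(ifelse(names(d) %in% names(spec$factors),
                                                            "factor", "covariate")),
                                             names(d)))
    X <- encode_matrix(d, terms, specs,
                       has_intercept = spec$family != "cox")$X
    if (length(spec$beta) != ncol(X))
      stop("beta has length ", length(spec$beta), " but the design implies ",
           ncol(X), " column(s): ", paste(colnames(X), collapse = ", "),
           call. = FALSE)
    eta <- drop(X %*% spec$beta)

    if (spec$family == "cox") {
      t_event <- stats::rexp(n) / (spec$baseline_rate * exp(eta))
      cmax <- spec$censor_max %||% unname(stats::quantile(t_event, 0.9) * 2)
      cens <- stats::runif(n, 0, cmax)
      d$time <- pmin(t_event, cens)
      d$status <- as.numeric(t_event <= cens)
    } else {
      d$y <- switch(spec$family,
        gaussian = stats::rnorm(n, eta, spec$sd),
        binomial = stats::rbinom(n, 1, 1 / (1 + exp(-eta))),
        poisson = stats::rpois(n, exp(eta)),
        gamma = {
          mu <- 1 / eta
          if (any(mu <= 0))
            stop("gamma generating eta must be positive (mu = 1/eta)",
                 call. = FALSE)
          stats::rgamma(n, shape = spec$shape, rate = spec$shape / mu)
        })
    }
    roles <- lapply(stats::setNames(names(d), names(d)), function(v) {
      if (v %in% names(spec$factors)) "factor"
      else if (v == "time") "time" else if (v == "status") "status"
      else "covariate"
    })
    specs_full <- specs_from_data(d, names(d), roles)
    new_bundle(d, specs_full, "synthetic",
               params = list(spec = spec, design_columns = colnames(X)),
               formula = formula)
  })
}
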