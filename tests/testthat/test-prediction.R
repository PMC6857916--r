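test_that("linear predictor and its standard error match hand matrix arithmetic", {
  d <- make_crab_data(200)
  m <- fit_model(d, crab_formula())
  lp <- linear_predictor(m, list(Width = 28, Dark = "yes"))
  xs <- c(1, 28, 1)
  expect_equal(lp$eta, sum(xs * m$beta), tolerance = 1e-12)
  expect_equal(lp$se_eta, sqrt(drop(t(xs) %*% m$sigma %*% xs)),
               tolerance = 1e-12)

  expect_error(linear_predictor(m, list(Width = 28, Dark = "purple")),
               "unseen level")
  expect_warning(linear_predictor(m, list(Width = 99, Dark = "yes")),
                 "outside the observed range")

  # degenerate covariance gives zero standard error
  m0 <- m; m0$sigma[] <- 0
  expect_equal(linear_predictor(m0, list(Width = 28, Dark = "yes"))$se_eta, 0)
})

test_that("intercept-only behaviour: constant terms contribute eta = beta0 + contributions", {
  withr::local_seed(21)
  d <- data.frame(x = rnorm(50))
  d$y <- 2.5 + rnorm(50, 0, 0.1)
  m <- fit_model(d, model_spec("y", "gaussian",
                               terms = list(term_covariate("x"))))
  lp0 <- linear_predictor(m, list(x = 0))
  expect_equal(lp0$eta, unname(m$beta[1]), tolerance = 1e-12)
})

test_that("confidence intervals use the right critical value and widen with level", {
  d <- make_crab_data(200)
  m <- fit_model(d, crab_formula())  # poisson: normal critical value
  ci <- confidence_interval(1.5, 0.2, 0.95, m)
  expect_equal(ci, c(1.5 - 1.959964 * 0.2, 1.5 + 1.959964 * 0.2),
               tolerance = 1e-6)
  expect_equal(confidence_interval(1.5, 0, 0.95, m), c(1.5, 1.5))

  ci99 <- confidence_interval(1.5, 0.2, 0.99, m)
  expect_lt(ci99[1], ci[1]); expect_gt(ci99[2], ci[2])

  # estimated dispersion switches to the t distribution
  withr::local_seed(22)
  dg <- data.frame(x = runif(25, 0.5, 2))
  dg$y <- dg$x + rnorm(25, 0, 0.2)
  mg <- fit_model(dg, model_spec("y", "gaussian",
                                 terms = list(term_covariate("x"))))
  cit <- confidence_interval(0, 1, 0.95, mg)
  expect_equal(cit[2], qt(0.975, df = mg$df_residual), tolerance = 1e-9)
})

test_that("inverse links match their closed forms and preserve ordering", {
  expect_equal(inverse_link("binomial", "logit", 0), 0.5)
  expect_equal(inverse_link("poisson", "log", 0), 1)
  expect_equal(inverse_link("gaussian", "identity", 3.7), 3.7)
  expect_equal(inverse_link("binomial", "logit", c(-2, 2)),
               c(exp(-2) / (1 + exp(-2)), exp(2) / (1 + exp(2))),
               tolerance = 1e-12)
  expect_equal(inverse_link("gamma", "inverse", 4), 0.25)
})

test_that("response-scale predictions respect interval ordering and family ranges", {
  d <- make_passenger_data(300)
  m <- fit_model(d, passenger_formula())
  p <- predict_response(m, list(age = 40, pclass = "1st", sex = "male"))
  expect_true(p$response_lower <= p$response_estimate)
  expect_true(p$response_estimate <= p$response_upper)
  expect_true(all(c(p$response_lower, p$response_estimate,
                    p$response_upper) >= 0))
  expect_true(all(c(p$response_lower, p$response_estimate,
                    p$response_upper) <= 1))

  # gaussian estimate equals hand x'beta
  withr::local_seed(23)
  dg <- data.frame(a = runif(80), b = runif(80))
  dg$y <- 1 + 2 * dg$a - dg$b + rnorm(80, 0, 0.3)
  mg <- fit_model(dg, model_spec("y", "gaussian",
                                 terms = list(term_covariate("a"),
                                              term_covariate("b"))))
  pg <- predict_response(mg, list(a = 0.4, b = 0.6))
  expect_equal(pg$response_estimate,
               sum(c(1, 0.4, 0.6) * mg$beta), tolerance = 1e-12)

  # gamma reciprocal link: decreasing transform swaps the limits coherently
  withr::local_seed(24)
  dgam <- data.frame(x = runif(150, 0.5, 2))
  dgam$y <- rgamma(150, shape = 4, rate = 4 * (0.5 + 0.6 * dgam$x))
  mgam <- fit_model(dgam, model_spec("y", "gamma",
                                     terms = list(term_covariate("x"))))
  pgam <- predict_response(mgam, list(x = 1))
  expect_true(pgam$response_lower <= pgam$response_estimate &
                pgam$response_estimate <= pgam$response_upper)
  expect_true(pgam$response_lower > 0)
})

test_that("average canonical-link prediction over training rows equals the response mean", {
  d <- make_passenger_data(250)
  m <- fit_model(d, passenger_formula())
  preds <- vapply(seq_len(nrow(d)), function(i)
    predict_response(m, as.list(d[i, c("age", "pclass", "sex")]))$response_estimate,
    numeric(1))
  expect_equal(mean(preds), mean(d$survived), tolerance = 1e-6)
})

test_that("survival curves are proper step functions anchored at 1", {
  m <- fit_model(cox3_data(), cox3_formula())
  # beta = 0 here, so the curve at the covariate mean is exp(-Nelson-Aalen)
  sc <- survival_curve(m, list(x = 0))
  expect_equal(sc$times, c(1, 2))
  expect_equal(sc$survival, exp(-c(1 / 3, 1 / 3 + 1 / 2)), tolerance = 1e-12)
  expect_equal(sc$at_risk_fraction, c(1, 2 / 3))
  expect_true(all(diff(sc$survival) <= 0))
  expect_true(all(sc$survival <= 1))

  # centering identity: any model, inputs at covariate means
  withr::local_seed(25)
  n <- 80
  dd <- data.frame(t = rexp(n, 0.1), s = rbinom(n, 1, 0.8), x = rnorm(n))
  mm <- fit_model(dd, model_spec(family = "cox", time = "t", status = "s",
                                 terms = list(term_covariate("x"))))
  scm <- survival_curve(mm, list(x = mean(dd$x)))
  expect_equal(scm$survival, exp(-breslow_baseline(mm)$cumhaz),
               tolerance = 1e-10)
})

test_that("survival at a time point carries a delta-method interval containing the estimate", {
  m <- fit_model(cox3_data(), cox3_formula())
  s <- survival_at(m, list(x = 0), t = 1)
  expect_equal(s$estimate, exp(-1 / 3), tolerance = 1e-12)
  # beta = 0, x at the mean: Var(Lambda) = sum d_j / n_j^2 = 1/9, so the
  # log-cumulative-hazard standard error is (1/3)/(1/3) = 1
  q <- qnorm(0.975)
  expect_equal(s$lower, exp(-(1 / 3) * exp(q)), tolerance = 1e-10)
  expect_equal(s$upper, exp(-(1 / 3) * exp(-q)), tolerance = 1e-10)
  expect_true(s$lower <= s$estimate && s$estimate <= s$upper)

  # level 0 collapses the interval onto the point
  s0 <- survival_at(m, list(x = 0), t = 1, level = 0)
  expect_equal(s0$lower, s0$estimate, tolerance = 1e-12)
  expect_equal(s0$upper, s0$estimate, tolerance = 1e-12)

  # before the first event survival is 1; beyond follow-up is an error
  expect_equal(survival_at(m, list(x = 0), t = 0.5)$estimate, 1)
  expect_error(survival_at(m, list(x = 0), t = 99), "beyond the last")
})

test_that("mean-response interval coverage is calibrated on synthetic logistic data", {
  # 95% CI for the mean response at a fixed x over replicated draws
  beta_true <- c(-0.4, 0.9)
  x_at <- 0.7
  true_mean <- plogis(beta_true[1] + beta_true[2] * x_at)
  reps <- 400
  n <- 500
  covered <- logical(reps)
  withr::local_seed(26)
  for (r in seq_len(reps)) {
    x <- runif(n, -1, 1.2)
    y <- rbinom(n, 1, plogis(beta_true[1] + beta_true[2] * x))
    d <- data.frame(x = x, y = y)
    m <- fit_model(d, model_spec("y", "binomial",
                                 terms = list(term_covariate("x"))))
    p <- predict_response(m, list(x = x_at))
    covered[r] <- p$response_lower <= true_mean & true_mean <= p$response_upper
  }
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.97)
})
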