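test_that("OLS interpolates noiseless data and matches the normal-equations oracle", {
  withr::local_seed(11)
  d <- data.frame(x = runif(40, 0, 10), w = rnorm(40))
  d$y <- 3 - 2 * d$x + 0.5 * d$w
  spec <- model_spec("y", "gaussian",
                     terms = list(term_covariate("x"), term_covariate("w")))
  m <- fit_model(d, spec)
  expect_equal(unname(m$beta), c(3, -2, 0.5), tolerance = 1e-10)
  expect_lt(m$rss, 1e-18)

  # noisy case against an independent normal-equations solve
  d$y <- d$y + rnorm(40)
  des <- build_design(d, spec)
  m2 <- fit_ols(des)
  X <- des$X
  beta_oracle <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(unname(m2$beta), drop(beta_oracle), tolerance = 1e-10,
               ignore_attr = TRUE)
  s2 <- sum((d$y - X %*% beta_oracle)^2) / (40 - 3)
  expect_equal(unname(m2$sigma), s2 * solve(t(X) %*% X), tolerance = 1e-9,
               ignore_attr = TRUE)

  # rank deficiency is reported with the offending column
  d$x2 <- 2 * d$x
  spec3 <- model_spec("y", "gaussian",
                      terms = list(term_covariate("x"), term_covariate("x2")))
  expect_error(fit_model(d, spec3), "rank deficient")
})

test_that("IRLS coincides with OLS for the gaussian/identity family", {
  withr::local_seed(12)
  d <- data.frame(x = runif(120, 0, 4), f = sample(c("a", "b"), 120, TRUE))
  d$y <- 1 + 2 * d$x - 0.7 * (d$f == "b") + rnorm(120, 0, 0.5)
  des <- build_design(d, model_spec("y", "gaussian",
                                    terms = list(term_covariate("x"),
                                                 term_factor("f"))))
  m_ols <- fit_ols(des)
  m_irls <- fit_glm_irls(des, family = "gaussian", link = "identity")
  expect_lt(max(abs(m_ols$beta - m_irls$beta)), 1e-8)
  expect_lt(max(abs(m_ols$sigma - m_irls$sigma)), 1e-8)
})

test_that("logistic IRLS matches a brute-force maximizer of the written-out likelihood", {
  withr::local_seed(13)
  n <- 20
  d <- data.frame(x = rnorm(n))
  d$y <- rbinom(n, 1, plogis(0.4 + 0.9 * d$x))
  des <- build_design(d, model_spec("y", "binomial",
                                    terms = list(term_covariate("x"))))
  m <- fit_glm_irls(des)
  nll <- function(b) {
    eta <- b[1] + b[2] * d$x
    -sum(d$y * eta - log(1 + exp(eta)))
  }
  oracle <- optim(c(0, 0), nll, method = "BFGS",
                  control = list(reltol = 1e-14))
  expect_lt(max(abs(unname(m$beta) - oracle$par)), 1e-5)
})

test_that("IRLS agrees with the reference GLM implementation across families", {
  withr::local_seed(14)
  n <- 300
  d <- data.frame(x = runif(n, 0, 3), f = sample(c("lo", "hi"), n, TRUE))
  d$yb <- rbinom(n, 1, plogis(-0.5 + 0.8 * d$x))
  d$yp <- rpois(n, exp(0.2 + 0.4 * d$x))
  d$yg <- rgamma(n, shape = 3, rate = 3 * (0.4 + 0.3 * d$x))

  cases <- list(
    list(resp = "yb", family = "binomial", ref = binomial()),
    list(resp = "yp", family = "poisson", ref = poisson()),
    list(resp = "yg", family = "gamma", ref = Gamma()))
  for (cs in cases) {
    spec <- model_spec(cs$resp, cs$family,
                       terms = list(term_covariate("x"), term_factor("f")))
    m <- fit_model(d, spec)
    g <- glm(stats::reformulate(c("x", "relevel(factor(f), 'hi')"), cs$resp),
             data = d, family = cs$ref)
    expect_equal(unname(m$beta), unname(coef(g)), tolerance = 1e-6)
    expect_equal(unname(sqrt(diag(m$sigma))), unname(sqrt(diag(vcov(g)))),
                 tolerance = 1e-4)
    # score equation at the optimum: for these links V(mu) * g'(mu) is
    # constant, so the score reduces to X'(y - mu) up to sign and dispersion
    y <- d[[cs$resp]]
    des <- build_design(d, spec)
    score <- crossprod(des$X, y - m$fitted)
    expect_lt(max(abs(score)), 1e-6 * nrow(d))
  }
})

test_that("IRLS rejects invalid responses and reports separation", {
  d <- data.frame(x = 1:20, y = rep(c(0, 1), 10))
  des <- build_design(d, model_spec("y", "binomial",
                                    terms = list(term_covariate("x"))))
  expect_error(fit_glm_irls(des, y = d$y + 0.5), "support")
  d2 <- data.frame(x = 1:20, y = rep(c(0, 1), each = 10))  # perfect separation
  des2 <- build_design(d2, model_spec("y", "binomial",
                                      terms = list(term_covariate("x"))))
  expect_error(fit_glm_irls(des2), "separation|converge|invalid")
})

test_that("Cox fit matches a 1-D grid-search oracle and is order invariant", {
  d <- cox8_data()
  spec <- model_spec(family = "cox", time = "time", status = "status",
                     terms = list(term_covariate("grp")))
  m <- fit_model(d, spec)
  # independent oracle: maximize the written-out partial likelihood on a grid
  beta_grid <- optimize(function(b) cox_pll_oracle(b, d$time, d$status, d$grp),
                        c(-4, 4), maximum = TRUE, tol = 1e-10)$maximum
  expect_lt(abs(unname(m$beta) - beta_grid), 1e-4)
  expect_equal(unname(m$loglik),
               cox_pll_oracle(unname(m$beta), d$time, d$status,
                              d$grp - mean(d$grp)),
               tolerance = 1e-8)

  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  m_perm <- fit_model(d[perm, ], spec)
  expect_equal(m_perm$beta, m$beta, tolerance = 1e-10)
})

test_that("Cox fit reproduces the reference implementation with Efron and Breslow ties", {
  withr::local_seed(15)
  skip_if_not_installed("survival")
  n <- 120
  d <- data.frame(t = round(rexp(n, 0.1)) + 1, s = rbinom(n, 1, 0.7),
                  a = rnorm(n), f = sample(c("x", "y"), n, TRUE))
  spec <- model_spec(family = "cox", time = "t", status = "s",
                     terms = list(term_covariate("a"), term_factor("f")))
  for (ties in c("efron", "breslow")) {
    m <- fit_model(d, spec, ties = ties)
    cf <- survival::coxph(survival::Surv(t, s) ~ a + relevel(factor(f), "x"),
                          data = d, ties = ties)
    expect_equal(unname(m$beta), unname(coef(cf)), tolerance = 1e-7)
    expect_equal(unname(sqrt(diag(m$sigma))), unname(sqrt(diag(vcov(cf)))),
                 tolerance = 1e-6)
  }
})

test_that("Cox coefficients are invariant to monotone time transforms and degenerate inputs error", {
  d <- cox8_data()
  spec <- model_spec(family = "cox", time = "time", status = "status",
                     terms = list(term_covariate("grp")))
  m1 <- fit_model(d, spec)
  d2 <- d; d2$time <- exp(d$time / 3)  # strictly increasing transform
  m2 <- fit_model(d2, spec)
  expect_equal(m1$beta, m2$beta, tolerance = 1e-9)

  d3 <- d; d3$status <- 0
  expect_error(fit_model(d3, spec), "no events")
  d4 <- d; d4$grp <- order(d$time)  # covariate perfectly ranks all subjects
  expect_error(fit_model(d4, spec), "monotone likelihood|singular")
})

test_that("Breslow baseline matches the hand Nelson-Aalen computation at beta = 0", {
  m <- fit_model(cox3_data(), cox3_formula())
  expect_equal(unname(m$beta), 0, tolerance = 1e-12)  # score at 0 is 0 by design
  base <- breslow_baseline(m)
  expect_equal(base$time, c(1, 2))
  expect_equal(base$cumhaz, c(1 / 3, 1 / 3 + 1 / 2), tolerance = 1e-12)
  expect_equal(base$n_risk, c(3, 2))
  expect_true(all(diff(base$cumhaz) >= 0))
  expect_true(all(diff(base$n_risk) <= 0))
})

test_that("Breslow baseline is invariant under subject replication", {
  withr::local_seed(16)
  n <- 60
  d <- data.frame(t = rexp(n, 0.2), s = rbinom(n, 1, 0.8), x = rnorm(n))
  spec <- model_spec(family = "cox", time = "t", status = "s",
                     terms = list(term_covariate("x")))
  # Breslow tie handling: doubling every subject rescales each risk-set sum
  # and event count together, leaving the maximizer and d_j / S0_j unchanged
  m1 <- fit_model(d, spec, ties = "breslow")
  m2 <- fit_model(rbind(d, d), spec, ties = "breslow")
  expect_equal(m1$beta, m2$beta, tolerance = 1e-6)
  b1 <- breslow_baseline(m1); b2 <- breslow_baseline(m2)
  expect_equal(b1$time, b2$time)
  expect_equal(b1$cumhaz, b2$cumhaz, tolerance = 1e-6)
})

test_that("model export/import round-trips and validates", {
  d <- make_crab_data(150)
  m <- fit_model(d, crab_formula())
  m2 <- import_model(export_model(m))
  p1 <- predict_response(m, list(Width = 28, Dark = "yes"))
  p2 <- predict_response(m2, list(Width = 28, Dark = "yes"))
  expect_identical(p1$response_estimate, p2$response_estimate)
  expect_identical(p1$se_eta, p2$se_eta)

  # asymmetric covariance is rejected
  bad <- jsonlite::fromJSON(export_model(m), simplifyVector = FALSE)
  bad$sigma[[1]][[2]] <- 99
  expect_error(import_model(jsonlite::toJSON(bad, auto_unbox = TRUE)),
               "symmetric")
  bad2 <- jsonlite::fromJSON(export_model(m), simplifyVector = FALSE)
  bad2$beta <- bad2$beta[-1]
  expect_error(import_model(jsonlite::toJSON(bad2, auto_unbox = TRUE)),
               "dimension mismatch")
})

test_that("a hand-written logistic model JSON predicts by the inverse logit", {
  obj <- list(
    format = "dynogram-model", version = 1, family = "binomial",
    link = "logit", response = "y", columns = list("(Intercept)", "x"),
    beta = c(-1, 2), sigma = list(c(0, 0), c(0, 0)),
    dispersion = 1, df_residual = 98, n_used = 100, loglik = 0,
    has_intercept = TRUE,
    terms = list(list(kind = "covariate", vars = list("x"))),
    variable_specs = list(list(name = "x", role = "covariate",
                               observed_min = -2, observed_max = 2, mean = 0)))
  m <- import_model(jsonlite::toJSON(obj, auto_unbox = TRUE))
  p <- predict_response(m, list(x = 0.5))
  expect_equal(p$response_estimate, plogis(-1 + 2 * 0.5), tolerance = 1e-12)
  expect_equal(p$se_eta, 0)
  expect_equal(p$response_lower, p$response_estimate)
})
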