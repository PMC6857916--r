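test_that("term contributions follow the coefficient definitions", {
  d <- make_crab_data(200)
  m <- fit_model(d, crab_formula())
  # reference level and zero covariate contribute nothing
  expect_equal(term_contribution(m, 2, "no"), 0)
  expect_equal(term_contribution(m, 1, 0), 0)
  expect_equal(term_contribution(m, 1, 28), unname(m$beta["Width"]) * 28,
               tolerance = 1e-12)
  expect_equal(term_contribution(m, 2, "yes"), unname(m$beta["Dark(yes)"]),
               tolerance = 1e-12)
})

test_that("spline term contribution equals the basis/coefficient dot product", {
  withr::local_seed(31)
  d <- data.frame(x = runif(300, 0, 100), w = rnorm(300))
  d$y <- 2 + 0.5 * d$w + sin(d$x / 15) + rnorm(300, 0, 0.3)
  m <- fit_model(d, model_spec("y", "gaussian",
                               terms = list(term_covariate("w"),
                                            term_spline("x", 5))))
  kn <- m$terms[[2]]$knots
  for (x0 in c(5, 33.3, 71, 96)) {
    oracle <- sum(rcs_basis(x0, kn) * m$beta[m$term_columns[[2]]])
    expect_equal(term_contribution(m, 2, x0), oracle, tolerance = 1e-12)
  }
})

test_that("ruler lengths follow the contribution-span ratios", {
  # two covariates with spans 5 and 2 give lengths 1.0 and 0.4
  withr::local_seed(32)
  d <- data.frame(a = runif(200, 0, 1), b = runif(200, 0, 1))
  # pin exact observed ranges [0, 1] before generating the response
  d$a[1:2] <- c(0, 1); d$b[1:2] <- c(0, 1)
  d$y <- 5 * d$a + 2 * d$b + rnorm(200, 0, 1e-6)
  m <- fit_model(d, model_spec("y", "gaussian",
                               terms = list(term_covariate("a"),
                                            term_covariate("b"))))
  la <- ruler_length(m, 1); lb <- ruler_length(m, 2)
  expect_equal(la, 1.0, tolerance = 1e-4)
  expect_equal(lb, 0.4, tolerance = 1e-4)
  expect_equal(max(la, lb), 1)  # normalization is exact

  # translation invariance: shifting a covariate leaves its span unchanged
  d2 <- d; d2$a <- d$a + 100
  m2 <- fit_model(d2, model_spec("y", "gaussian",
                                 terms = list(term_covariate("a"),
                                              term_covariate("b"))))
  expect_equal(ruler_length(m2, 1), la, tolerance = 1e-4)

  # rescaling a covariate with a correspondingly rescaled coefficient too
  d3 <- d; d3$a <- d$a * 10
  m3 <- fit_model(d3, model_spec("y", "gaussian",
                                 terms = list(term_covariate("a"),
                                              term_covariate("b"))))
  expect_equal(ruler_length(m3, 1), la, tolerance = 1e-4)

  # single-term model is self-normalized to 1
  m1 <- fit_model(d, model_spec("y", "gaussian",
                                terms = list(term_covariate("a"))))
  expect_equal(ruler_length(m1, 1), 1)
})

test_that("layouts reproduce predictions through the points path for every model class", {
  withr::local_seed(33)
  n <- 300
  base <- data.frame(x = runif(n, 0, 3), f = sample(c("p", "q", "r"), n, TRUE))
  mk <- function(resp, family) {
    d <- base; d$y <- resp
    fit_model(d, model_spec("y", family,
                            terms = list(term_covariate("x"),
                                         term_factor("f"))))
  }
  eta <- 0.3 + 0.5 * base$x - 0.4 * (base$f == "q") + 0.6 * (base$f == "r")
  models <- list(
    gaussian = mk(eta + rnorm(n, 0, 0.4), "gaussian"),
    binomial = mk(rbinom(n, 1, plogis(eta - 1)), "binomial"),
    poisson = mk(rpois(n, exp(eta - 0.5)), "poisson"),
    # reciprocal link needs a positive linear predictor over the support
    gamma = mk(rgamma(n, 3, rate = 3 * (eta + 0.5)), "gamma"))
  dcx <- base
  dcx$t <- rexp(n) / (0.1 * exp(0.4 * base$x - 0.3 * (base$f == "q")))
  dcx$s <- as.numeric(dcx$t < quantile(dcx$t, 0.8))
  dcx$t <- pmin(dcx$t, quantile(dcx$t, 0.8))
  models$cox <- fit_model(dcx, model_spec(family = "cox", time = "t",
                                          status = "s",
                                          terms = list(term_covariate("x"),
                                                       term_factor("f"))))
  for (nm in names(models)) {
    m <- models[[nm]]
    L <- build_layout(m)
    expect_equal(max(vapply(L$axes, `[[`, numeric(1), "max_points")), 100,
                 tolerance = 1e-9)
    for (r in 1:50) {
      xn <- list(x = runif(1, 0, 3), f = sample(c("p", "q", "r"), 1))
      tp <- total_points(L, m, xn)
      ref <- if (nm == "cox") exp(linear_predictor(m, xn)$eta)
             else predict_response(m, xn)$response_estimate
      expect_lt(abs(tp$response - ref), 1e-6)
    }
  }
})

test_that("stratified axes serve factor interactions; covariate pairs and splines are refused", {
  d <- make_passenger_data(400)
  m <- fit_model(d, passenger_formula(interactions = TRUE))
  L <- build_layout(m)
  # age x pclass x sex collapse to one group: 6 stratified age axes
  expect_identical(length(L$axes), 6L)
  for (r in 1:20) {
    xn <- list(age = runif(1, 1, 80),
               pclass = sample(c("1st", "2nd", "3rd"), 1),
               sex = sample(c("female", "male"), 1))
    expect_lt(abs(total_points(L, m, xn)$response -
                    predict_response(m, xn)$response_estimate), 1e-6)
  }

  withr::local_seed(34)
  d2 <- data.frame(a = runif(150), b = runif(150))
  d2$y <- d2$a * d2$b + rnorm(150, 0, 0.2)
  m2 <- fit_model(d2, model_spec("y", "gaussian",
                                 terms = list(term_covariate("a"),
                                              term_covariate("b"),
                                              term_interaction(c("a", "b")))))
  expect_error(build_layout(m2), "covariate-by-covariate")
})

test_that("single-term layouts span exactly 100 points", {
  withr::local_seed(35)
  d <- data.frame(x = runif(100, 0, 1))
  d$y <- 2 * d$x + rnorm(100, 0, 0.1)
  m <- fit_model(d, model_spec("y", "gaussian",
                               terms = list(term_covariate("x"))))
  L <- build_layout(m)
  expect_equal(L$total_points_range, c(0, 100), tolerance = 1e-9)
})

test_that("rendered SVG is well-formed, axis-complete, and byte-stable", {
  # deterministic toy model: exact integer data, no RNG
  d <- data.frame(x = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                  f = rep(c("ctl", "trt"), 5),
                  y = c(2, 5, 5, 9, 9, 13, 12, 17, 16, 21))
  m <- fit_model(d, model_spec("y", "gaussian",
                               terms = list(term_covariate("x"),
                                            term_factor("f"))))
  L <- build_layout(m)
  svg <- render_svg(L, options = list(title = "toy nomogram"))

  expect_identical(svg, render_svg(L, options = list(title = "toy nomogram")))

  skip_if_not_installed("xml2")
  doc <- xml2::read_xml(svg)
  expect_identical(xml2::xml_name(doc), "svg")
  # one ruler line per axis + points scale + total points + response
  lines <- xml2::xml_find_all(doc, "//*[local-name()='line'][@class='ruler']")
  expect_identical(length(lines), length(L$axes) + 3L)

  golden <- test_path("fixtures", "golden-nomogram.svg")
  expect_identical(svg, paste(readLines(golden), collapse = "\n"))
})
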