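# Shared fixtures, all generated in code.

# passenger-style data: one covariate, a 3-level factor, a 2-level factor,
# binary outcome with known coefficients
make_passenger_data <- function(n = 400, seed = 42) {
  withr::local_seed(seed)
  d <- data.frame(
    age = runif(n, 1, 80),
    pclass = sample(c("1st", "2nd", "3rd"), n, replace = TRUE),
    sex = sample(c("female", "male"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  eta <- 1.2 - 0.02 * d$age - 1.0 * (d$pclass == "2nd") -
    1.8 * (d$pclass == "3rd") - 2.4 * (d$sex == "male")
  d$survived <- rbinom(n, 1, plogis(eta))
  d
}

passenger_formula <- function(interactions = FALSE) {
  terms <- list(term_covariate("age"), term_factor("pclass"),
                term_factor("sex"))
  if (interactions)
    terms <- c(terms, list(term_interaction(c("age", "pclass")),
                           term_interaction(c("age", "sex")),
                           term_interaction(c("pclass", "sex"))))
  model_spec("survived", "binomial", terms = terms)
}

# crab-style count data: width covariate + binary colour factor
make_crab_data <- function(n = 250, seed = 7) {
  withr::local_seed(seed)
  d <- data.frame(
    Width = runif(n, 21, 33.5),
    Dark = sample(c("no", "yes"), n, replace = TRUE, prob = c(0.7, 0.3)),
    stringsAsFactors = FALSE)
  d$Satellites <- rpois(n, exp(-2.8 + 0.15 * d$Width - 0.27 * (d$Dark == "yes")))
  d
}

crab_formula <- function() {
  model_spec("Satellites", "poisson",
             terms = list(term_covariate("Width"), term_factor("Dark")))
}

# 3-subject survival fixture whose partial-likelihood score at beta = 0 is
# exactly zero (so the fit lands on beta = 0 and the baseline is the
# Nelson-Aalen estimator): events at t = 1, 2; censored at t = 3
cox3_data <- function() {
  data.frame(time = c(1, 2, 3), status = c(1, 1, 0), x = c(2, -3, 1))
}

cox3_formula <- function() {
  model_spec(family = "cox", time = "time", status = "status",
             terms = list(term_covariate("x")))
}

# 8-subject binary-covariate survival fixture with distinct event times,
# used against a 1-D grid-search oracle on the written-out partial likelihood
cox8_data <- function() {
  data.frame(time = c(1, 2, 3, 4, 5, 6, 7, 8),
             status = c(1, 1, 0, 1, 1, 0, 1, 1),
             grp = c(1, 0, 1, 1, 0, 0, 1, 0))
}

# independent written-out Cox partial log-likelihood (Breslow form; the
# fixture has no ties so it equals the Efron form)
cox_pll_oracle <- function(beta, time, status, x) {
  ll <- 0
  for (i in which(status == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# independent written-out restricted-cubic basis at a single point
rcs_oracle_point <- function(x, knots) {
  k <- length(knots)
  t1 <- knots[1]; tkm1 <- knots[k - 1]; tk <- knots[k]
  pp <- function(u) max(u, 0)^3
  vals <- numeric(k - 1)
  vals[1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    vals[j + 1] <- (pp(x - tj) - pp(x - tkm1) * (tk - tj) / (tk - tkm1) +
                      pp(x - tk) * (tkm1 - tj) / (tk - tkm1)) / (tk - t1)^2
  }
  vals
}
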