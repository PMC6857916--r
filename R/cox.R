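# partial log-likelihood, score and information for centered covariates Z,
# with Efron or Breslow handling of tied event times. Returns the pieces the
# Newton-Raphson loop and the baseline-hazard estimator both need.
cox_loglik <- function(Z, time, status, beta, ties) {
  n <- nrow(Z); p <- ncol(Z)
  ord <- order(time)
  Z <- Z[ord, , drop = FALSE]
  time <- time[ord]; status <- status[ord]
  eta <- drop(Z %*% beta)
  e <- exp(eta)

  # suffix sums over the risk set {l : time_l >= t}: S0 scalar, S1 p-vector,
  # S2 p x p (stored as p^2 columns)
  S0 <- rev(cumsum(rev(e)))
  S1 <- apply(Z * e, 2L, function(col) rev(cumsum(rev(col))))
  S1 <- matrix(S1, nrow = n, ncol = p)
  ZZ <- matrix(0, n, p * p)
  for (a in seq_len(p)) for (b in seq_len(p))
    ZZ[, (a - 1L) * p + b] <- Z[, a] * Z[, b] * e
  S2 <- apply(ZZ, 2L, function(col) rev(cumsum(rev(col))))
  S2 <- matrix(S2, nrow = n, ncol = p * p)

  ev_times <- unique(time[status == 1])
  ll <- 0; grad <- numeric(p); info <- matrix(0, p, p)
  for (t_j in ev_times) {
    at_risk_idx <- match(TRUE, time >= t_j)  # first index in risk set
    D <- which(time == t_j & status == 1)
    d <- length(D)
    s0 <- S0[at_risk_idx]
    s1 <- S1[at_risk_idx, ]
    s2 <- matrix(S2[at_risk_idx, ], p, p)
    eD <- e[D]
    ll <- ll + sum(eta[D])
    if (ties == "breslow" || d == 1L) {
      ll <- ll - d * log(s0)
      grad <- grad + colSums(Z[D, , drop = FALSE]) - d * s1 / s0
      info <- info + d * (s2 / s0 - tcrossprod(s1 / s0))
    } else {
      s0D <- sum(eD)
      s1D <- colSums(Z[D, , drop = FALSE] * eD)
      s2D <- crossprod(Z[D, , drop = FALSE] * sqrt(eD))
      grad <- grad + colSums(Z[D, , drop = FALSE])
      for (r in seq_len(d) - 1L) {
        f <- r / d
        den <- s0 - f * s0D
        num1 <- s1 - f * s1D
        num2 <- s2 - f * s2D
        ll <- ll - log(den)
        grad <- grad - num1 / den
        info <- info + num2 / den - tcrossprod(num1 / den)
      }
    }
  }
  list(loglik = ll, grad = grad, info = info,
       ord = ord, time = time, status = status, e = e, S0 = S0, S1 = S1,
       ev_times = ev_times)
}

#' Cox proportional hazards fit
#'
#' Maximises the partial log-likelihood by Newton-Raphson with step halving,
#' using the Efron correction for tied event times by default (Breslow
#' available). The coefficient covariance is the inverse observed
#' information, and the baseline cumulative hazard is the Breslow estimator
#' evaluated with covariates centered at their means.
#'
#' @param design a [build_design()] result for a `family = "cox"`
#'   specification (no intercept).
#' @param time,status event time (positive) and status (1 = event,
#'   0 = censored) vectors; default from the design.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   change.
#' @param max_iter iteration cap.
#' @return a fitted model of classes `dn_cox`, `dn_model`, carrying the
#'   baseline table (`time`, `n_event`, `n_risk`, `s0`, `cumhaz`).
#' @export
fit_cox <- function(design, time = design$time, status = design$status,
                    ties = c("efron", "breslow"), tol = 1e-9, max_iter = 50L) {
  ties <- match.arg(ties)
  X <- design$X
  if (design$has_intercept)
    stop("cox design must not contain an intercept", call. = FALSE)
  if (!all(status %in% c(0, 1))) stop("status must be 0/1", call. = FALSE)
  if (!any(status == 1)) stop("no events (status == 1) in the data", call. = FALSE)
  if (any(time <= 0)) stop("event times must be positive", call. = FALSE)

  xbar <- colMeans(X)
  Z <- sweep(X, 2L, xbar)
  p <- ncol(Z)
  beta <- numeric(p)
  state <- cox_loglik(Z, time, status, beta, ties)
  for (iter in seq_len(max_iter)) {
    step <- tryCatch(solve(state$info, state$grad),
                     error = function(e) stop(
                       "singular information matrix: a covariate may perfectly rank the events (monotone likelihood)",
                       call. = FALSE))
    # step halving if the likelihood does not improve
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      cand_state <- cox_loglik(Z, time, status, cand, ties)
      if (cand_state$loglik >= state$loglik - 1e-12 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    delta <- max(abs(cand - beta))
    beta <- cand; state <- cand_state
    if (max(abs(beta)) > 500)
      stop("coefficients diverging: monotone likelihood suspected (a covariate perfectly ranks the events)",
           call. = FALSE)
    if (delta < tol) break
    if (iter == max_iter)
      stop("Cox fit failed to converge in ", max_iter, " iterations",
           call. = FALSE)
  }

  sigma <- solve(state$info)
  base <- breslow_baseline_state(state)
  out <- new_model(design, beta, sigma, dispersion = NA_real_,
                   df_residual = sum(status == 1) - p, loglik = state$loglik,
                   extra = list(ties = ties, covariate_means = xbar,
                                n_events = sum(status == 1),
                                baseline = base,
                                max_follow_up = max(time),
                                iterations = iter))
  class(out) <- c("dn_cox", class(out))
  out
}

# Breslow baseline cumulative hazard and at-risk counts from a converged
# cox_loglik state (covariates centered at their means)
breslow_baseline_state <- function(state) {
  time <- state$time; status <- state$status
  ev <- state$ev_times
  n_event <- vapply(ev, function(t) sum(time == t & status == 1), numeric(1))
  n_risk <- vapply(ev, function(t) sum(time >= t), numeric(1))
  s0 <- vapply(ev, function(t) state$S0[match(TRUE, time >= t)], numeric(1))
  s1 <- do.call(rbind, lapply(ev, function(t)
    state$S1[match(TRUE, time >= t), , drop = FALSE]))
  data.frame(time = ev, n_event = n_event, n_risk = n_risk, s0 = s0,
             cumhaz = cumsum(n_event / s0),
             s1 = I(s1))
}

#' Breslow baseline cumulative hazard
#'
#' Returns the step baseline cumulative hazard at each distinct event time,
#' `Lambda0(t) = sum over event times up to t of d_j / sum over the risk set
#' of exp((x - xbar) beta)`, together with the at-risk counts used for
#' alpha-blending in survival displays.
#'
#' @param model a fitted `dn_cox` model.
#' @return data frame with columns `time`, `n_event`, `n_risk`, `cumhaz`.
#' @export
breslow_baseline <- function(model) {
  stopifnot(inherits(model, "dn_cox"))
  model$baseline[c("time", "n_event", "n_risk", "cumhaz")]
}
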