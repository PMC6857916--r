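---
title: "Nomograms from regression models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nomograms from regression models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynogram)
```

## What the package computes

A nomogram is a graphical `predict` function. Each predictor in a fitted
regression model gets a ruler that converts its value (or level) into
*points*; the reader sums the points across rulers and converts the total,
through two further rulers, into a prediction on the response scale. A
*dynamic* nomogram replaces the paper rulers with input controls — sliders
for covariates bounded by their observed ranges, drop-downs for factors —
and displays the point prediction together with its confidence interval for
any scenario the user dials in.

dynogram implements the whole pipeline on its own statistical engine:

1. **Design matrices** with treatment-contrast factors, restricted cubic
   splines and product interactions (`build_design()`).
2. **Fitting**: closed-form least squares, iteratively reweighted least
   squares (IRLS) for the logistic, Poisson and gamma families, and
   Newton-Raphson maximisation of the Cox partial likelihood with a Breslow
   baseline hazard (`fit_model()`).
3. **Prediction**: mean-response estimates with confidence intervals mapped
   through the inverse link, and survival curves with delta-method
   intervals for Cox models (`predict_response()`, `survival_at()`).
4. **Static geometry**: point rulers scaled by relative contribution span,
   rendered to SVG (`build_layout()`, `render_svg()`).
5. **The dynamic session**: accumulated scenarios, numerical and model
   summaries, and hermetic deployable bundles (`nomogram_session()`,
   `export_bundle()`).

## The model classes and their confidence intervals

The supported families are the canonical-link generalised linear models —
gaussian/identity, binomial/logit, Poisson/log, gamma/reciprocal — plus the
Cox proportional hazards model. For a new observation
$x_*^T = (1, x_1, \dots, x_p)$ the engine forms the linear predictor
$\hat\eta = x_*^T\hat\beta$ and its standard error
$\sqrt{x_*^T \hat\Sigma x_*}$, builds the interval on the linear scale,

$$\hat\eta \pm u_{1-\alpha/2}\sqrt{x_*^T \hat\Sigma x_*},$$

and maps the estimate and both limits through the inverse link
$g^{-1}$ (identity, $e^\eta/(1+e^\eta)$, $e^\eta$, or $1/\eta$). Because
every supported inverse link is monotone, the mapped limits are again an
interval; for the decreasing reciprocal link the limits swap. A
reciprocal-link interval that straddles zero has no defined mean response
and is reported as an error rather than silently clipped.

**Critical value.** $u_{1-\alpha/2}$ is a standard-normal quantile when the
dispersion is known (binomial, Poisson, Cox) and a Student-$t$ quantile on
the residual degrees of freedom when it is estimated (gaussian, gamma).
This is the package's resolution of an underdetermined choice; at the
sample sizes where nomograms are sensible the two are nearly
indistinguishable.

**Gamma link.** The reciprocal link is implemented as $\mu = 1/\eta$, the
standard parameterisation; the sign-flipped variant $\eta = -\mu^{-1}$
differs only by the sign of the coefficients.

## Fitting: numerical choices

*IRLS* iterates weighted least squares with weights
$w = (d\mu/d\eta)^2 / V(\mu)$ and working response
$z = \eta + (y-\mu)/( d\mu/d\eta)$, solved by QR decomposition, until the
largest coefficient change falls below $10^{-9}$ (at most 50 iterations,
which in practice means 4-8). Iteration starts from the adjusted
observations ($\mu_0 = y$ with the usual family-specific adjustments),
not from a zero coefficient vector: with the reciprocal link, a poor start
can converge to a stationary point with negative fitted means, while the
observation-based start keeps the whole path inside the valid region. A
candidate step whose coefficients exceed $10^4$ in absolute value aborts
with a separation diagnosis; rank-deficient designs abort naming the
collinear columns.

Dispersion is fixed at 1 for binomial and Poisson, estimated as
$\mathrm{RSS}/(n-p)$ for gaussian and by the Pearson statistic over
$(n-p)$ for gamma. The coefficient covariance is
$\hat\phi\,(X^TWX)^{-1}$ at the final weights.

*Cox* fits use Newton-Raphson with step-halving on the partial
log-likelihood, with the **Efron** tie correction by default (Breslow
available as an option); the covariance is the inverse observed
information. Covariates are centred at their means before fitting the
baseline: the Breslow estimator

$$\hat\Lambda_0(t) = \sum_{t_j \le t} \frac{d_j}{\sum_{i \in R(t_j)}
e^{(x_i-\bar x)\hat\beta}}$$

is then numerically stable, and predictions rescale by
$e^{(x_*-\bar x)\hat\beta}$. Predicted survival at a time point gets its
interval on the log-cumulative-hazard scale by the delta method, combining
the baseline variance $\sum_{t_j\le t} d_j/S_0(t_j)^2$ with the
coefficient-covariance term, then back-transforms through
$S = \exp(-\Lambda)$ — symmetric on the transformed scale and guaranteed to
land in $[0,1]$. A monotone likelihood (a covariate that perfectly ranks
the events) is detected by coefficient divergence or a singular
information matrix and reported as an error.

## Restricted cubic splines

Non-linear covariate effects use the restricted ("natural") cubic spline in
the truncated-power parameterisation: with knots $t_1 < \dots < t_k$,
column 1 is $x$ itself and column $j+1$ ($j = 1,\dots,k-2$) is

$$\frac{(x-t_j)_+^3 - (x-t_{k-1})_+^3\frac{t_k-t_j}{t_k-t_{k-1}}
      + (x-t_k)_+^3\frac{t_{k-1}-t_j}{t_k-t_{k-1}}}{(t_k-t_1)^2},$$

which is linear beyond the boundary knots by construction and normalised by
the squared boundary span so all columns live on the scale of $x$. Default
knots sit at the conventional quantiles (for $k=5$: 0.05, 0.275, 0.5,
0.725, 0.95). This particular basis was chosen because it is the
parameterisation under which published spline coefficient tables for this
kind of model are reproducible; other natural-spline bases span the same
function space but print different coefficients. Knots are frozen into the
fitted model, so new observations and serialized models encode identically.

## Static layout: generalising the ruler-length rule

The classic rule assigns ruler $i$ the relative length
$\mathrm{range}(X_i)\,\beta_i / \max_i[\mathrm{range}(X_i)\,\beta_i]$. That
expression only covers linear covariate terms, so the package generalises
it to the **contribution span**: the max-minus-min of the term's
contribution to the linear predictor over its observed support (covariate
endpoints, all factor levels, a 100-point grid for splines). The dominant
term spans exactly 100 points; each axis is offset so its minimum
contribution sits at 0 points. Summing axis points and mapping the total
through the linear predictor and the inverse link reproduces
`predict_response()` to within $10^{-6}$ — a consistency identity the test
suite checks on every model class.

Interactions need care. A factor-involved interaction is drawn as
*stratified axes*: one covariate ruler per factor-level combination, with
the factor main effects folded into the strata so the points still sum to
the linear predictor. Two stratification choices are refused because no
faithful flat ruler exists: covariate-by-covariate interactions (the
contribution is a surface, not a curve) and interactions involving a
spline; both are directed to the dynamic interface instead. The response
ruler carries up to 7 "nice" values spanning the achievable response range;
for Cox layouts, which have no intercept, the response scale is the
relative hazard $e^{\eta}$ about the covariate means.

SVG rendering is deliberately dumb: pure string assembly with fixed
formatting, so identical layouts yield byte-identical files.

## The dynamic session and its service contract

The interactive layer performs no statistics. A session holds a model and
an ordered list of scenarios; `add_scenario()` routes each input set
through `predict_response()` (or `survival_curve()`), and every number a
UI displays — tooltip, plot, numerical summary — comes from those calls.
The view-model (`view_model()`) is a JSON-ready structure of controls,
scenario results and summary tables, so any front end can host it; the
package ships a console host (`serve_session()`) as the reference
implementation of that contract.

Cox scenarios plot step survival curves whose opacity encodes uncertainty:
the alpha value at time $t$ is $\max(0.1,\; n_{\text{at risk}}(t)/n)$. The
floor keeps the curve tail legible where the risk set has nearly emptied;
the mapping is the package's own choice, since only the idea of
risk-set-proportional blending is established.

`export_bundle()` writes the serialized model (coefficients, covariance,
frozen variable specifications and knots, baseline hazard for Cox), the
control configuration, a runnable entry script and an md5 manifest. The
bundle never references the training data — hermeticity is tested by
deleting the training CSV and requiring bit-identical predictions.
Serialization uses 17 significant digits, which round-trips doubles
exactly.

## Synthetic data: what it emulates and what it does not

`generate_synthetic()` draws covariates (normal or uniform), factors with
stated level probabilities, forms $\eta = X\beta$ with user-chosen
coefficients, and draws the response from the family: gaussian noise,
Bernoulli with $\text{logit}^{-1}(\eta)$, Poisson with $e^\eta$, gamma
with a stated shape and mean $1/\eta$, and for Cox exponential event times
with hazard $\lambda_0 e^\eta$ under uniform censoring. Every bundle
records its generating spec and seed, and generation leaves the caller's
RNG stream untouched.

These fixtures give every test known truth, but they are idealised: the
linear predictor is exactly correct, covariates are independent, censoring
is uninformative, and the Cox baseline is constant. Passing tests
therefore demonstrate that the *algorithms* are correct and calibrated
under their own assumptions — not that any particular real dataset
satisfies those assumptions.

The verification suite runs at deliberately moderate problem sizes, chosen
as the smallest that make the stochastic checks sharp: coefficient
recovery uses 200 replicates of $n = 2000$ per family (each estimate
required within 3 standard errors of the truth in at least 95% of
replicates), and interval coverage uses 1000 replicates of $n = 500$
(empirical coverage required in $[0.92, 0.97]$ for the nominal 95%).

## Worked examples and external data

`fetch_example()` returns the four classic datasets used as verification
surfaces, typed and paired with their published model specifications. Two
resolve from locally installed packages with no network (the Titanic
passengers and the advanced lung cancer cohort); the horseshoe-crab and
ragweed-pollen datasets are downloaded from their CRAN source packages,
cached, and checksum-verified on every subsequent load (the checksum is
recorded at first fetch). The ragweed bundle applies the square-root
transform to the pollen response as part of the fixture, matching the
published preprocessing. All fetched examples are optional: every other
test in the package runs offline on synthetic fixtures.

Missing data are handled by complete-case deletion only, with the dropped
count reported — no imputation. Factor levels order lexicographically with
the first level as reference unless an explicit ordering is declared (the
lung example declares `male` as reference so the published
`sex(female)` contrast appears).

## Known limitations

- No offsets, observation weights, penalised smoothers, ordered or
  polynomial contrasts; the intercept is always present for GLMs.
- No robust/sandwich covariances, stratified Cox models, time-varying
  covariates or frailty terms.
- Intervals are for the *mean* response, not for new observations, and are
  pointwise, not simultaneous.
- Static layouts refuse covariate-by-covariate and spline interactions by
  design; the dynamic interface covers those models.
- Extrapolation beyond a covariate's observed range warns rather than
  errors (interactive controls are bounded anyway, but the prediction API
  is not).
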