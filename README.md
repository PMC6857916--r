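# dynogram

Nomograms — static and dynamic — from regression models, on a
self-contained statistical engine.

## The problem

A fitted regression model is only useful to a clinician, a patient or a
policy maker if its predictions are accessible. A **nomogram** makes a
model readable: each predictor gets a ruler converting its value or level
into *points*, the points are summed, and two final rulers convert the
total into a prediction on the response scale (a probability, a count, a
mean). Its **dynamic** counterpart replaces paper rulers with sliders and
drop-downs and shows, for any scenario, the predicted response together
with its confidence interval — which static rulers cannot carry, and which
matters as soon as models contain interactions or smooth terms.

dynogram is for anyone who builds clinical or epidemiological prediction
models and wants to publish them as something people can use: it fits the
model, draws the static nomogram, drives the interactive version, and
exports a deployable bundle that no longer needs the training data.

## The statistics

Supported model classes: linear regression, logistic, Poisson and gamma
regression (canonical links), and the Cox proportional hazards model.
All fitting is done in-package — ordinary least squares by QR, the GLM
families by iteratively reweighted least squares, Cox by Newton–Raphson on
the partial likelihood (Efron tie correction by default) with a Breslow
baseline cumulative hazard. Designs may contain factors
(treatment contrasts), restricted cubic splines, and interactions of up to
three variables.

For a new observation $x_*^T = (1, x_1, \dots, x_p)$, the mean-response
interval is built on the linear scale,

$$\hat\eta \pm u_{1-\alpha/2}\,\sqrt{x_*^T\hat\Sigma\,x_*},
\qquad \hat\eta = x_*^T\hat\beta ,$$

and mapped through the inverse link $g^{-1}$ (identity,
$e^\eta/(1+e^\eta)$, $e^\eta$, $1/\eta$). Cox models get predicted
survival curves $S(t\mid x) = \exp\{-\hat\Lambda_0(t)\,
e^{(x-\bar x)\hat\beta}\}$ with delta-method intervals on the
log-cumulative-hazard scale, and curves are alpha-blended by the fraction
of subjects still at risk.

Static ruler lengths follow the classic proportionality rule
$\mathrm{range}(X_i)\beta_i / \max_i[\mathrm{range}(X_i)\beta_i]$,
generalised to the contribution span so factors and splines get rulers
too. The methods vignette (`vignettes/nomograms.Rmd`) documents every
numerical choice.

## A worked example

The advanced lung cancer cohort (228 patients; available offline through
the survival package) with a Cox model of age, weight loss, ECOG
performance score and sex:

```r
library(dynogram)

b <- fetch_example("lung")       # typed table + the published model spec
m <- fit_model(b$table, b$formula)
model_summary(m)
#> Family: cox   n = 213   loglik = -659.51
#>         term  estimate std_error z_value   p_value hazard_ratio hr_lower hr_upper
#>          age  0.013370  0.009628   1.389 1.650e-01       1.0130   0.9945   1.0330
#>      wt.loss -0.009006  0.006658  -1.353 1.761e-01       0.9910   0.9782   1.0040
#>      ph.ecog  0.515100  0.126000   4.089 4.341e-05       1.6740   1.3080   2.1430
#>  sex(female) -0.590800  0.175300  -3.369 7.535e-04       0.5539   0.3928   0.7811
```

Each unit of ECOG score multiplies the hazard of death by 1.67; being
female halves it (HR 0.55). Predicted survival for a specific patient at a
specific follow-up time:

```r
survival_at(m, list(age = 60, wt.loss = 10, ph.ecog = 1, sex = "male"), t = 250)
#> S(250 days) = 0.559  [0.470, 0.639]
```

The same flow drives GLMs. The Titanic passengers (offline via carData),
logistic model of age, class and sex:

```r
t <- fetch_example("titanic")
mt <- fit_model(t$table, t$formula)
predict_response(mt, list(age = 40, pclass = "1st", sex = "male"))
#> <prediction> age=40, pclass=1st, sex=male
#>   estimate 0.4130  [0.3428, 0.4869]  (95% CI)
```

A 40-year-old man with a first-class ticket had an estimated 41% chance of
surviving. The static nomogram for that model:

```r
L <- build_layout(mt)
#> <nomogram layout> 3 axes, total points 0..274.4
#>   age        0..100.0 points
#>   pclass     0..83.4 points
#>   sex        0..91.0 points
write_svg(L, "titanic-nomogram.svg")
```

All three rulers have comparable lengths — age, class and sex contribute
similarly over their observed spans. The dynamic version accumulates
scenarios and exports a hermetic bundle:

```r
s <- nomogram_session(mt)
s <- add_scenario(s, list(age = 40, pclass = "1st", sex = "male"))
s <- add_scenario(s, list(age = 40, pclass = "3rd", sex = "male"))
numerical_summary(s)
export_bundle(mt, "titanic-app")   # model.json + config + entry script + manifest
```

A command-line interface over the same functions ships at
`inst/cli/dynogram.R` (`fit`, `predict`, `nomogram`, `bundle`, `serve`,
`fetch-example`).

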