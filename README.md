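# tmlesurv

Targeted maximum likelihood estimation (TMLE) of the causal effect of a
point binary or multilevel exposure on a time-to-event outcome, for
epidemiologists and biostatisticians working with observational cohorts
under confounding and missing-at-random censoring.

Follow-up is discretized into `K` intervals and the package estimates, with
efficient-influence-curve Wald inference:

* **Counterfactual survival curves** `S_a(t) = P(T_a > t)` — the fraction of
  the population that would remain event-free through interval `t` had
  everyone received exposure `a` — via an iterated-conditional-expectation
  backward recursion with a weighted-regression targeting (fluctuation)
  step at every interval;
* **Average treatment effects** `ATE(t) = S_1(t) − S_0(t)`;
* **Marginal structural model (MSM) coefficients** for the discrete-time
  hazard, `logit[λ_a(t)] = X_{a,t}ᵀ γ` with
  `λ_a(t) = (S_a(t−1) − S_a(t)) / S_a(t−1)`, fitted by weighted logistic
  regression of the estimated hazards with weights `Ŝ_a(t−1)` and a
  delta-method influence curve for `Var(γ̂)`.

The estimator is **doubly robust**: consistent if either the event
regressions or the exposure-plus-censoring models are correctly specified.
Nuisance models can be parametric logistic regressions or a cross-validated
stacking ensemble (mean / logistic / interactions-and-squares logistic /
spline additive model) with convex weights chosen by non-negative least
squares on the out-of-fold squared error and an adaptive fold count.
Near-positivity violations are controlled by flooring the weight-denominator
probabilities at `gbound`.

A benchmark synthetic-data generator with closed-form ground truth
(`dgp_params()`, `simulate_survival_data()`, `true_survival()`,
`true_msm_coefficients()`) supports simulation studies and powers the test
suite.

## Worked example

```r
library(tmlesurv)

d <- simulate_survival_data(5000, seed = 1)   # benchmark DGP, K = 4
curve <- tmle_survival_curve(d)               # parametric nuisance models
curve
#> TMLE counterfactual survival estimates (n = 5000):
#>  a t estimate       se ci_low ci_high n_truncated
#>  0 1   0.8664 0.004992 0.8566  0.8761           0
#>  1 1   0.9551 0.011302 0.9329  0.9772           0
#>  0 2   0.7537 0.006333 0.7413  0.7661           0
#>  1 2   0.9062 0.016709 0.8735  0.9390           0
#>  0 3   0.6501 0.007023 0.6363  0.6639           0
#>  1 3   0.8531 0.020932 0.8121  0.8941           0
#>  0 4   0.5668 0.007309 0.5525  0.5812           0
#>  1 4   0.8031 0.023444 0.7572  0.8491           0
```

Each row is `Ŝ_a(t)` with its influence-curve standard error and 95% Wald
interval; the true values here are 0.87/0.75/0.65/0.56 (`a = 0`) and
0.95/0.90/0.85/0.80 (`a = 1`). `n_truncated` counts weight-denominator
probabilities floored at `gbound`.

```r
r1 <- curve$results[[which(curve$estimates$a == 1 & curve$estimates$t == 4)]]
r0 <- curve$results[[which(curve$estimates$a == 0 & curve$estimates$t == 4)]]
tmle_ate(r1, r0)
#> TMLE ATE(4) = S_1 - S_0 = 0.2363 (95% CI 0.1882-0.2844)

tmle_msm(curve)                               # default MSM: ~ a + factor(t)
#> Marginal structural model for the discrete-time hazard
#> (exp(estimate) is an odds ratio; ~ hazard ratio only for small hazards)
#>  coefficient estimate      se  ci_low ci_high exp_estimate
#>  (Intercept) -1.92096 0.07257 -2.0632 -1.7787       0.1465
#>            a -1.00697 0.13715 -1.2758 -0.7382       0.3653
#>   factor(t)2  0.01601 0.12198 -0.2231  0.2551       1.0161
#>   factor(t)3  0.10852 0.12978 -0.1458  0.3629       1.1146
#>   factor(t)4  0.05860 0.13484 -0.2057  0.3229       1.0603
```

The exposure coefficient `γ̂_a = −1.01` (true projected value −1.00)
estimates the log odds ratio of the per-interval event under exposure; the
time indicators let the baseline hazard vary by interval.
`plot_survival(curve)` draws the step-style curves with confidence bands.

Real datasets enter through `read_wide_survival()` (wide CSV, one row per
subject, cumulative `Y_t`/`C_t` indicators) or `discretize_followup()`
(continuous follow-up times plus terminal status). `run_pipeline()` drives
the whole analysis from a JSON configuration, and `inst/cli/tmlesurv.R` is a
thin command-line front end with `simulate` / `validate` / `fit` / `plot`
subcommands.

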