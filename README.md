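# aaiiw

Multiply robust estimation of the marginal causal effect of a time-varying
binary treatment on a continuous longitudinal outcome that is observed only
at **irregular, covariate-driven visit times** — the situation of electronic
health records, where an outcome exists in the data only when the patient
shows up, and showing up depends on treatment, confounders, mediators and
symptoms.

Two spurious association channels must be removed at once: confounding of
the treatment–outcome relationship, and selection induced by the visit
process. The package estimates the parameters of the marginal structural
model

```
E[Y^a(t)] = beta0 + beta1 * a
```

where `beta1 = E[Y^1(t) - Y^0(t)]` is the marginal treatment effect, using
the **doubly augmented, doubly inverse weighted (AAIIW)** estimating
equations

```
sum_{visit rows}   eta_i(t) / E[dN | V]
  - sum_{at-risk rows} dM_i(t) * g_ia(t) / E[dN | V]  = 0 ,   a in {0, 1}

eta  = 1{A=a} Y / P_a  - (1{A=a} - P_a)/P_a * mu_a{K} - (beta0 + beta1 a)
dM   = dN - xi(t) * lambda0(t) exp(gamma' V)            (visit martingale)
g_ia = eta with Y replaced by mu_a{V}                    (its E[. | A, K, V])
```

built from four nuisance models: the treatment propensity `P{A=1|K}`, a
proportional-rate (Andersen–Gill, Breslow baseline) or logistic visit model
`E[dN|V]`, and two conditional outcome means `mu_a{K}`, `mu_a{V}`. The
estimator is consistent when **any one** of four combinations is correctly
specified — (propensity + visit), (both outcome means), (`mu_a{K}` +
visit), (propensity + `mu_a{V}`) — and is more efficient than the doubly
weighted (FIPTM) estimator when all four are correct. OLS, IPT-weighted and
doubly weighted comparators, inverse-probability-of-censoring weights for
informative dropout, subject-level bootstrap intervals and Rubin's-rules
pooling are included, together with a synthetic cohort generator whose true
marginal effect is known exactly — so every claim the package makes is
testable without external data.

## Worked example

```r
library(aaiiw)

cfg    <- scenario_config(n = 1000, tau = 90, gamma = "setB")  # truth: beta1 = 1
cohort <- generate_cohort(cfg, seed = 42)
cohort$panel
#> person-time panel: 1000 subject(s), 91000 person-days, tau = 90
#>   visits: 5875 (6.46% of at-risk days)

fit_and_estimate(cohort$panel, "OLS")
#> OLS estimate of the marginal structural model
#>   beta0 (untreated mean) = 0.6509
#>   beta1 (marginal treatment effect) = 1.3023

fit_and_estimate(cohort$panel, "DW_c")      # doubly weighted comparator
#>   beta1 (marginal treatment effect) = 1.1081

fit_and_estimate(cohort$panel, "AAIIW_c")   # augmented, all models correct
#>   beta0 (untreated mean) = 1.2869
#>   beta1 (marginal treatment effect) = 1.0134

bootstrap_ci(cohort$panel, function(d) fit_and_estimate(d, "AAIIW_c"),
             B = 50, seed = 1)
#> beta1 = 1.0134, 95% bootstrap percentile CI (0.9464, 1.1108), B = 50
```

On this cohort the visit process (`setB`) pulls visits strongly toward low
mediator values and treatment is confounded by `K1, K2`: the naive
arm-means estimator reports 1.30 for a true effect of 1, the doubly
weighted estimator 1.11, and the augmented estimator 1.01 with a bootstrap
interval covering the truth.

Monte Carlo experiments over the full estimator grid (five augmented
robustness scenarios, four weighting comparators, four visit-process
presets, optional informative censoring) run through `run_scenario()` /
`summarize_simulation()`, or from a shell via the thin CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","aaiiw_cli.R",package="aaiiw"))')" \
    scenario --preset setB --reps 200 --seed 7 --outdir results/
```

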