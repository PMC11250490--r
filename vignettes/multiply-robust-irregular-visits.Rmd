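---
title: "Multiply robust estimation of a marginal treatment effect under irregular, covariate-driven visits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiply robust estimation of a marginal treatment effect under irregular, covariate-driven visits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Electronic health records measure outcomes only when a patient visits, and
patients visit for reasons tied to their own state: the sicker, the more
recently treated, the more symptomatic patients are seen more often. Two
spurious association channels therefore threaten the estimation of a
marginal treatment effect from such data: classical confounding of the
treatment--outcome relationship, and selection induced by the visit process
(conditioning on "a visit happened" conditions on a collider when both
treatment and outcome drive visits).

`aaiiw` estimates the marginal causal effect $\beta_1 =
E[Y^1_i(t) - Y^0_i(t)]$ of a time-varying binary treatment $A_i(t)$ on a
continuous outcome $Y_i(t)$ observed only at visit days, under a marginal
structural model with constant effect,

$$E[Y^a_i(t)] = \zeta(\beta_a) = \beta_0 + \beta_1 a .$$

Data are a discrete-time person-day panel: at most one visit per day
(`visit` = the counting-process increment $dN_i(t)$), an at-risk indicator
$\xi_i(t) = 1\{t < C_i\}$, confounders $K$, a treatment-affected mediator
$M$, a pure outcome/visit predictor $P$, and the visit-predictor set
$V = (A, K_1, K_2, M, P)$, which must contain the confounders.

Identification requires outcome consistency, positivity of treatment and of
observation, no unmeasured confounding given $K$, and independence of the
visit indicator from treatment and potential outcomes given $V$
("observation at random").

## Estimators

Four nuisance models enter the machinery:

* the treatment propensity $P\{A(t)=1 \mid K(t)\}$ (logistic),
* the visit model $E[dN(t) \mid V(t)]$, either a proportional-rate
  (Andersen--Gill) model $\xi(t)\exp\{\gamma^\top V(t)\}\lambda_0(t)$ with a
  Breslow step-function baseline, or a logistic model of the daily visit
  probability,
* two conditional outcome means $\mu_a\{K\} = E[Y \mid A=a, K]$ and
  $\mu_a\{V\} = E[Y \mid A=a, V]$ (linear).

**Comparators.** `estimate_dw()` covers the ordinary least squares, IPT-only,
and doubly weighted (FIPTM) estimators: per arm, a weighted mean of the
observed outcomes over visit rows with weight
$\frac{1\{A=a\}}{\hat P\{A=a\mid K\}} \cdot \frac{1}{\hat E[dN\mid V]}$.
For the doubly weighted comparator the visit mean may be *stabilized*
($\exp\{\hat\gamma^\top V\}$, baseline cancelled); that shortcut is legal
there because a common per-day factor drops out of the weighted means, but
not for the augmented estimator below, which needs the absolute intensity.

**AAIIW.** The doubly augmented, doubly inverse weighted estimator solves,
per arm $a$,

$$\sum_{\text{visit rows}} \frac{\eta_i(t)}{\hat E[dN\mid V]}
 \;-\; \sum_{\text{at-risk rows}}
 \frac{dM_i(t)\, \hat g_{ia}(t)}{\hat E[dN\mid V]} = 0,$$

with
$\eta = \frac{1\{A=a\}}{\hat P_a} Y - \frac{1\{A=a\}-\hat P_a}{\hat P_a}
\hat\mu_a\{K\} - \zeta(\beta_a)$, the martingale residual
$dM = dN - \xi \hat\lambda_0(t) e^{\hat\gamma^\top V}$, and
$\hat g_{ia} = \frac{1\{A=a\}}{\hat P_a}\hat\mu_a\{V\} -
\frac{1\{A=a\}-\hat P_a}{\hat P_a}\hat\mu_a\{K\} - \zeta(\beta_a)$.
Both equations are linear in $\zeta$ and solved in closed form (the
$\zeta$-coefficient reduces to the at-risk person-time at event days); an
iterative root solver is retained as a verification path. $\beta_0$ comes
from the arm-0 equation and is plugged into the arm-1 solution.

The estimator is consistent when any one of four combinations of correctly
specified nuisance models holds: (a) propensity + visit, (b) both outcome
means, (c) $\mu_a\{K\}$ + visit, (d) propensity + $\mu_a\{V\}$.

### Design choices that were genuinely open

**The conditional expectation in the augmentation.** $\hat g_{ia}$ is
$E[\eta \mid A, K, V]$ evaluated at the row's *observed* treatment arm:
$\eta$ with the outcome replaced by its $V$-conditional mean. An alternative
reading evaluates the expectation as a counterfactual prediction at level
$a$ on every row. Only the observed-arm form makes the augmentation cancel
the first term exactly whenever $\mu_a\{V\}$ is correct, independently of
the visit model — the cancellation that drives robustness combinations (b)
and (d). Our Monte Carlo experiments confirmed the choice decisively: with
the at-level-$a$ form, the all-correct estimator drifts far from the truth
as soon as the fitted visit intensity is imperfect, while the observed-arm
form is unbiased in every scenario. The observed-arm form is therefore the
implemented contract.

**Fitting the two outcome means.** Visits depend on predictors beyond $K$,
so an unweighted regression on visit rows targets the visit-selected mean
$E[Y \mid A, K, dN=1] \neq \mu_a\{K\}$. `fit_nuisance()` therefore fits
$\mu_a\{K\}$ with inverse-intensity weights from the estimator's own visit
model, and $\mu_a\{V\}$ unweighted (conditioning on all of $V$ already
restores exchangeability of the visit indicator). A consequence worth
knowing: in robustness scenario (b) the visit model is misspecified, so the
weights under the $\mu_a\{K\}$ fit are wrong; in the generator below the
induced error is a constant shift (the selection tilt of a normal mediator
is mean-independent), which cancels in $\beta_1 = \zeta_1 - \zeta_0$.

**Breslow denominator.** The baseline rate uses the risk-set denominator
$\hat\lambda_0(t) = \sum_i dN_i(t) \big/ \sum_{i \in \text{risk set}}
e^{\hat\gamma^\top V_i(t)}$, which makes the per-day martingale residuals
sum to zero exactly — the identity the augmentation term relies on. A
variant restricting the denominator sum to that day's visit rows appears in
print; it is available as `breslow_baseline(..., denominator = "events")`
for comparison but breaks the zero-sum identity and is not used for
estimation.

**Normalisation of the weighted comparators.** `estimate_dw()` defaults to
per-arm weighted means (the weighted-least-squares, Hájek form), which is
how a doubly weighted least squares estimator is computed in practice and
has smaller finite-sample variance. `normalize = FALSE` gives the literal
unnormalised estimating equation, in which the structural mean is counted
on every visit row with weight $1/\hat E[dN \mid V]$; that is the exact
algebraic limit of the AAIIW equations when both outcome means and the
martingale residuals are zeroed, and the reduction identity is asserted in
the test suite against that form.

## Censoring and IPCW

Subjects may drop out. Under the informative mechanism the generator draws,
on every day $t \ge 1$, a dropout event with hazard
$\operatorname{expit}\{c^\top V_i(t)\}$ evaluated at that day's covariates;
the dropout-day row is retained in the panel with `at_risk = 0` and no
visit, mirroring records in which measurements exist on the day a patient
leaves. That retained row matters twice. First, because every time-varying
variable in the generator is redrawn daily, dropout driven by *lagged*
covariates would be ignorable for $\beta_1$ (the constant effect holds in
every subpopulation); selection on the current day's $(A, M, P)$ is what
induces genuine bias, through the within-day collider between treatment and
the mediator/predictor noise among survivors. Second, it makes the per-day
censoring model identifiable: `ipcw_weights()` regresses the observed
dropout indicator on the same-day covariates and accumulates
$w_i(t) = 1 \big/ \prod_{s \le t} \hat P\{\text{uncensored at } s \mid
V_i(s)\}$.

For estimation (`fit_and_estimate()` labels suffixed `+IPCW`) the censoring
weights multiply into *every* nuisance fit as well as into both sums of the
estimating equations. Weighting the equations alone is not enough: the
nuisance fits would still target censoring-selected populations, and in our
experiments that residual selection left roughly half the bias in place.
The estimation route uses *stabilized* weights (marginal survival in the
numerator), which have near-unit mean at every day and sharply smaller
variance; under the constant-effect structural model the day-mixture they
induce is harmless. Truncation of the cumulative survival is available
(`floor`, default 0.01, truncations counted) as a positivity diagnostic,
but the estimation route sets an effectively inactive floor of $10^{-6}$:
with heavy dropout the cohort-wide survival crosses any sizable floor
mid-follow-up, and truncation then reintroduces the selection the weights
exist to remove — an effect we measured directly against oracle weights.

## The synthetic cohort generator

`generate_cohort()` draws, per subject and day ($t = 0, \dots, \tau$,
default $\tau = 90$, $n = 1000$):

* $K_1 \sim \text{Bernoulli}(0.55)$, $K_2 \sim N(0,1)$ at baseline, carried
  forward;
* $A(t) \sim \text{Bernoulli}(\operatorname{expit}(-0.4 + 0.8 K_1 + 0.6
  K_2))$, redrawn each day (the simplest mechanism consistent with a
  time-varying treatment; persistence is not needed for any claim tested);
* mediator $M(t) \sim N(0.5 A + 0.3 K_1, 0.5^2)$, predictor
  $P(t) \sim N(0, 1)$;
* visit with probability $\min\{1, \exp(\gamma^\top V)\}$
  (discretised nonhomogeneous Poisson rate) or
  $\operatorname{expit}(\gamma^\top V)$ (Bernoulli family), with
  $\gamma$ from presets `setA`–`setD`; `setA` is the uninformative rate
  $(0,0,0,0,0,-5)$;
* outcome $Y = 1 + 0.7 A + 0.4 K_1 + 0.4 K_2 + 0.6 M + 0.5 P + N(0,1)$,
  recorded at visit days only.

The direct treatment coefficient is derived so the marginal effect is
exactly `beta1_total` (default 1): $0.7 + 0.5 \times 0.6 = 1$. Potential
outcomes re-evaluate the mediator and outcome equations at both arms with
shared noise, so $Y^1 - Y^0$ equals the truth on every person-day, and
outcome consistency holds row-wise by construction.

**Calibration of the mediator scale.** The rate family is only a valid
probability model while $\exp(\gamma^\top V) < 1$; with a unit mediator
scale the strongest preset pushes roughly 5% of person-days past that
bound, so the "correctly specified" proportional-rate model would be
materially wrong in its own generating mechanism and the robustness
scenarios that rely on it would be contaminated by an artefact of the
generator rather than a property of the estimator. The default
`mediator_sd = 0.5` keeps the clipped fraction below ~0.2% across all
presets (and makes daily visits appropriately rare for a rate model,
roughly a 4–7% daily visit probability).

**Informative-censoring preset.** `censor_coefs = (A{=}0.8, K_1{=}0.2,
K_2{=}0.2, M{=}1.2, P{=}1.0, \text{intercept}{=}-3.8)`, a mean daily hazard
around 5–8% — a heavy-dropout cohort with mean follow-up near 11 days of
90. The coefficients were fixed from a design analysis (strong loading on
the outcome-relevant $M$ and $P$ with a treatment term, producing an
unadjusted bias of several hundredths via the within-day collider) before
any estimator comparisons, and not revisited.

What the generator does *not* emulate: temporal persistence in treatment,
mediator or predictor; covariate-driven treatment *timing*; measurement
error; outcome-dependent visits beyond $V$ (visits never depend on $Y$
given $V$, so "observation at random" holds by construction). Passing tests
therefore demonstrate the estimating-equation theory under its stated
assumptions, not robustness to their violation.

## Numerical and procedural choices

* Time is a 0-based integer grid with $dt = 1$; integrals against $dN$ are
  sums over visit rows, integrals against $dt$ sums over at-risk rows.
* Within-day ties in the proportional-rate fit use the Breslow convention,
  matching the baseline estimator.
* $dM / \hat E[dN \mid V]$ is defined as 0 on days carrying no visits at
  all ($\hat\lambda_0 = 0$ and $dN = 0$: a 0/0 limit).
* Estimating-equation solutions are closed-form; residuals above $10^{-8}$
  raise an error. Degenerate designs (an arm without visit rows, a single
  treatment level, fitted propensities at 0/1) raise labelled errors.
* Bootstrap confidence intervals resample *subjects* (all rows travel
  together) and refit every nuisance model per replicate; percentile
  bounds. Rubin's rules pool externally produced per-imputation estimates.
* IPT and IIV weights are used untruncated by default, matching the
  estimating-equation theory; weight diagnostics (min/mean/max) are
  attached to every estimate.

## Problem sizes

The simulation harness defaults to the study scale $n = 1000$, $\tau = 90$.
The packaged test suite runs the robustness matrix at 50 replicates per
cell, the censoring comparison at 500 replicates, and the efficiency
comparison at $n = 500$ with 400 paired replicates; `scripts/acceptance.R`
uses 200 replicates for the bias targets and 500 for the censoring target.
All bounds are phrased in the run's own Monte Carlo standard error, so they
adapt to the replicate count. These sizes are the package's choices for a
routine desk-scale run; larger runs via `run_scenario()` only tighten the
Monte Carlo error.

## Limitations

* The structural model assumes a constant treatment effect; under effect
  modification in time the estimand is a weighted time-average.
* Nuisance models are parametric (logistic / proportional-rate / linear);
  no machine-learning fits or cross-fitting.
* No sandwich variances: uncertainty comes from the subject-level
  bootstrap.
* The IPCW route assumes dropout-day covariates are recorded; with truly
  unobserved dropout-day states, censoring driven by the current day's
  covariates is not identifiable from the panel.
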