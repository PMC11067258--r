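---
title: "Estimating IOM-concordant health care disparities by deweighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating IOM-concordant health care disparities by deweighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deweight)
```

## The problem

The Institute of Medicine (IOM) defines a health care disparity as a group
difference in care that is *not* due to health status, clinical needs, or
preferences. Operationally this splits the covariates in two: health-status
variables $X^h$ (severity scores, labs, comorbidity), whose group
differences must be adjusted away, and socioeconomic-status (SES) variables
$X^s$ (education, income), whose group differences are part of the
disparity and must be preserved. Standard propensity-score weighting
balances *all* covariates and therefore over-adjusts; weighting on a
health-status-only propensity score leaves SES uncontrolled in the weights
and still distorts each group's SES distribution whenever SES and health
status are correlated.

`deweight` implements a two-score solution. With $Z \in \{0, 1\}$ the
minority indicator and $e(x) = \Pr(Z = 1 \mid X = x)$, the balancing
weights for a selection function $g$ are
$\omega_1^B(x) = g(x)/e(x)$ and $\omega_0^B(x) = g(x)/\{1 - e(x)\}$.
Dividing them by the analogous weights built from the SES-only score
$e(x^s)$ gives the deweighting weights

$$\omega_z(x) = \frac{\omega_z^B(x)}{\omega_z^B(x^s)}, \qquad z = 0, 1.$$

Weighting each group by $\omega_z$ produces target populations that share a
common conditional distribution of health status given SES while each group
keeps its own marginal SES distribution — exactly the IOM requirement. The
disparity estimate is the Hájek difference of weighted outcome means

$$\hat\tau_g = \frac{\sum_i \omega_1(X_i) Z_i Y_i}{\sum_i \omega_1(X_i) Z_i}
 - \frac{\sum_i \omega_0(X_i) (1 - Z_i) Y_i}{\sum_i \omega_0(X_i)(1 - Z_i)},$$

which is invariant to rescaling either group's weights; weights are
therefore stored unnormalized.

Three tilts are supported, with $g$ applied identically to $e(x)$ and
$e(x^s)$:

| estimand | $g(e)$     | $\omega_1(x)$ | $\omega_0(x)$ | target population |
|----------|------------|---------------|---------------|-------------------|
| ATE      | $1$        | $e(x^s)/e(x)$ | $\{1-e(x^s)\}/\{1-e(x)\}$ | combined |
| ATT      | $e$        | $1$           | $\frac{e(x)}{1-e(x)} \big/ \frac{e(x^s)}{1-e(x^s)}$ | minority |
| ATO      | $e(1-e)$   | $\{1-e(x)\}/\{1-e(x^s)\}$ | $e(x)/e(x^s)$ | overlap |

Because race is not manipulable the estimand is descriptive — a weighted
average controlled difference — and no causal identification assumptions
are invoked; positivity of both scores is still required for finite
weights.

## Fitting the two scores

The SES covariates are categorical, so the SES-only model with all main
effects and interactions is **saturated**: `fit_ses_ps()` returns the
minority proportion of each SES subgroup. Subgroups are the distinct
observed SES combinations, indexed lexicographically (`.g` in the data),
so the index is reproducible across runs and row orders. A subgroup without
both groups represented is a positivity error, never silently clipped.

The full score is fitted **within each SES subgroup** on the main effects
of the health-status covariates (`fit_ps(model = "full")`), because the
quantity that must be balanced is the conditional distribution of health
status given SES; stratum fits balance within strata far better than a
pooled main-effects model. Two estimators are available:

* `"ml"` — maximum-likelihood logistic regression (`stats::glm.fit`,
  IRLS tolerance $10^{-12}$). With overlap (ATO) weights, stratified ML
  yields *exact* within-stratum balance of all modeled covariates.
* `"cbps"` (default) — the just-identified covariate-balancing propensity
  score: coefficients solve the balance equations
  $\sum_i \{Z_i/e_i - (1-Z_i)/(1-e_i)\} x_i = 0$ (ATE) or
  $\sum_i \{Z_i - (1-Z_i) e_i/(1-e_i)\} x_i = 0$ (ATT) exactly, so the
  corresponding weighted means balance at machine precision. The
  just-identified variant was chosen because the method's value rests on
  near-exact finite-sample balance; the over-identified variant trades that
  exactness for efficiency and is out of scope. For the ATO the ML fit is
  returned unchanged, since overlap weights already attain exact balance
  there.

Numerically, the balance equations are solved as a convex minimization:
both systems are the stationarity conditions of an exponential-tilting dual
objective ($\mathrm{mean}[Z e^{-\eta} + (1-Z) e^{\eta} - (2Z-1)\eta]$ for
the ATE, $\mathrm{mean}[(1-Z) e^{\eta} - Z\eta]$ for the ATT, with
$\eta = x^\top\beta$), so a damped Newton iteration with Armijo
backtracking, started at the ML coefficients, converges globally whenever a
balancing solution exists. Columns are rescaled to unit standard deviation
internally for conditioning and the coefficients back-transformed; the
stopping rule is max-norm of the mean-form residual below $10^{-8}$
(at most 200 iterations). When the minority covariate mean lies outside the
convex hull of the majority points in a small stratum, no exact solution
exists; the fit then fails naming the stratum, and
`on_stratum_error = "pool"` opts into a pooled health-status fallback for
that stratum, reported in the convergence records (`tidy()` of the fit).
Propensities are used untrimmed — values outside $[10^{-6}, 1 - 10^{-6}]$
produce a warning, not a truncation — because the method is defined without
trimming and silent truncation would bias the balance guarantees.

## Diagnostics: is a weight set IOM-concordant?

Three absolute standardized mean differences (ASMDs), all with
*unweighted* standard-deviation denominators, measure the two halves of
the IOM requirement:

* $D_1$, $D_0$ (`ses_alteration()`): for each SES covariate, the absolute
  difference between the group's unweighted and weighted means, divided by
  that group's unweighted SD — how much the weights alter the group's own
  SES distribution. Constant weights give exactly 0.
* $D_r$ (`subgroup_health_balance()`): within SES subgroup $r$, the
  absolute difference of weighted minority and majority means of each
  health covariate, divided by the pooled unweighted within-subgroup SD.

`concordance_report()` assembles all three in long format and flags any
entry above 0.1 (the conventional imbalance threshold); a flagged weight
set "may not achieve the IOM definition". Two edge policies are explicit
design choices: a zero-SD denominator reports the metric as 0 with a
`degenerate` flag (a constant covariate carries no imbalance information
and must not crash a batch report), and $D_r$ cells where either group has
fewer than 2 subjects in the stratum are flagged `insufficient_n`, excluded
from flagging, and listed. Binary covariates enter all formulas as numeric
0/1, so the metrics are invariant to affine recoding.

## Inference

The variance is a fixed-weight Taylor linearization of the two Hájek
means with independent groups,
$\widehat{\mathrm{Var}}(\hat\tau_g) = V_1 + V_0$ with
$V_z = \sum_{i \in z} w_i^2 (Y_i - \hat\mu_z)^2 / (\sum_{i \in z} w_i)^2$,
and normal-quantile intervals. This matches standard survey-package
behavior; uncertainty from estimating the propensity scores is deliberately
ignored (the usual practice for these weights — and, for estimated rather
than known scores, typically conservative). A subject-resampling bootstrap
within groups (`ci_method = "bootstrap"`) is available as a cross-check;
under unit weights the linearization reduces to the familiar two-proportion
formula with the $n$ (not $n-1$) convention. The package's replicate study
(500 synthetic replicates at $n = 2000$) observes empirical coverage close
to the nominal 95%.

## The synthetic generator and its oracle

`sim_config()` / `simulate_disparity()` draw
$Z \sim \mathrm{Bern}(p)$, an SES cell from a race-specific joint table,
health covariates from a multivariate normal whose mean is shifted by both
race and SES (shared covariance), and a Bernoulli outcome that is logistic
in race, SES and health status. The defaults mimic the *shape* of the
right-heart-catheterization application that motivates the package: a 17.1%
minority share; two binary SES variables with race-specific marginals
(0.186/0.116 minority, 0.304/0.258 majority — the education and income
rates of that study's groups) joined by a within-race odds ratio of 5.7
(the association observed in that study's pooled SES table); five health
covariates with AR(1) correlation 0.3, race shifts of magnitude 0.2–0.5 SD
and SES shifts of magnitude 0.1–0.3 SD (moderate, realistic confounding);
and outcome coefficients giving roughly 40–45% prevalence. These are
structural choices fixed once; the generator makes no claim to reproduce
the real data's joint distribution. Features of real data it deliberately
lacks — missingness, measurement error, non-Gaussian clinical variables,
unmeasured SES — mean that passing tests certify the *estimators and
diagnostics*, not robustness to real-data pathologies.

Because the generative factorization is known, both true scores are
available analytically via Bayes' rule (`true_propensity()`): the SES score
from the cell tables, and the full score by adding the Gaussian
log-likelihood ratio, which is linear in $x^h$ since the covariance is
shared — so the fitted per-stratum logistic models are correctly specified.
`oracle_truth()` evaluates the estimand by Monte Carlo on a large simulated
population using the *true* scores and *true* conditional outcome means
(no outcome noise), with a ratio-linearization MC standard error scaling
as $1/\sqrt{n_{\text{oracle}}}$; the oracle never touches the estimation
path it validates.

## Problem sizes used in the validation suite

The test suite certifies exact-balance identities at $n \approx 2000$
(solver tolerances $10^{-6}$–$10^{-8}$), estimator recovery against a
$10^6$-draw oracle at $n = 10^5$ within 3 combined Monte-Carlo standard
errors for all three estimands, interval coverage over 500 replicates at
$n = 2000$, and the independence reduction (deweighting agreeing with
health-status-only weighting when SES shifts are zero) at $n = 10^5$.
Three health covariates are used in most replicate studies — enough to
exercise every code path while keeping per-stratum fits well conditioned
at realistic stratum sizes.

## Known limitations

* The SES model must be saturated (categorical SES); continuous SES
  variables would require a modeled SES score, which is out of scope.
* Small SES strata can lack an exact balancing solution (ATT/ATE CBPS) or
  enough subjects per group for $D_r$; the package surfaces both rather
  than papering over them, and the pooled fallback is opt-in.
* Confidence intervals ignore propensity-estimation uncertainty, and only
  independent-subject designs are supported (no clustering).
* Only the three named tilts (ATE/ATT/ATO) are offered; the alteration
  metrics protect *measured* SES only.

## A complete analysis in six calls

```{r, eval = FALSE}
cfg <- sim_config(n = 5000)
d   <- simulate_disparity(cfg, seed = 42)

unadjusted_difference(d)

w <- disparity_weights(d, estimand = "att", method = "deweighting")
estimate_disparity(d, w)

rep <- concordance_report(d, list(
  deweight = w,
  sshs = disparity_weights(d, estimand = "att", method = "sshs_ps")
))
attr(rep, "concordance")
autoplot(rep)

weighted_characteristics(d, w)
```
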