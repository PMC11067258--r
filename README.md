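# deweight

Propensity-score estimation of health care disparities that is concordant
with the Institute of Medicine (IOM) definition: a disparity is a group
difference in care **not** due to health status or clinical need — so
health-status covariates must be adjusted away while each group's
socioeconomic-status (SES) distribution is preserved.

Conventional weighting fails this requirement in one of two ways: weights
from the full propensity score $e(x) = \Pr(Z=1 \mid X=x)$ balance SES too,
over-adjusting the disparity; weights from a health-status-only score still
distort SES whenever SES and health status are correlated. `deweight`
implements the *deweighting* construction: balancing weights from the full
score divided by balancing weights from the SES-only score,

$$\omega_z(x) = \frac{\omega_z^B(x)}{\omega_z^B(x^s)},\qquad
\omega_1^B = \frac{g}{e},\quad \omega_0^B = \frac{g}{1-e},$$

for the ATE ($g = 1$), ATT ($g = e$) and ATO ($g = e(1-e)$) tilts. The
weighted groups then share a common conditional distribution of health
status given SES while keeping their own marginal SES distributions, and
the disparity is the Hájek difference of weighted outcome means.

The package provides:

* a tidy data contract (`as_disparity_data()`, `read_disparity_data()`)
  with SES-subgroup construction, plus the preprocessing recipe for the
  public right-heart-catheterization study table (`rhc_recipe()`);
* propensity fitting by maximum likelihood or just-identified
  covariate-balancing score (CBPS), pooled or stratified by SES subgroup
  (`fit_ps()`, `fit_ses_ps()`, `fit_cbps()`, `fit_logistic_ml()`);
* deweighting and comparator weights (`disparity_weights()`,
  `deweighting_weights()`, `comparator_weights()`, `weight_summary()`);
* Hájek disparity estimates with linearization or bootstrap intervals
  (`estimate_disparity()`, `unadjusted_difference()`), and weighted
  target-population characteristics (`weighted_characteristics()`);
* IOM-concordance diagnostics $D_1$, $D_0$, $D_r$ with 0.1-threshold
  flagging and a love plot (`concordance_report()`, `autoplot()`);
* a synthetic generator with analytically known true propensities and a
  Monte-Carlo oracle for the estimands (`sim_config()`,
  `simulate_disparity()`, `true_propensity()`, `oracle_truth()`).

See `vignettes/deweighting-disparities.Rmd` for the model, the solver, and
every numerical policy.

## Worked example

```r
library(deweight)

cfg <- sim_config(n = 5000)          # RHC-shaped synthetic study
d   <- simulate_disparity(cfg, seed = 42)

unadjusted_difference(d)
#> # disparity_est: crude / unadjusted
#> estimate 3.75 percentage points (95% CI 0.11 to 7.40), se 1.859
#> group means: minority 0.4584, majority 0.4209 (n = 866 / 4134)
#> p-value 0.044

w <- disparity_weights(d, estimand = "att", method = "deweighting")
estimate_disparity(d, w)
#> # disparity_est: att / deweighting
#> estimate -6.06 percentage points (95% CI -10.22 to -1.90), se 2.124
#> group means: minority 0.4584, majority 0.5190 (n = 866 / 4134)
```

Crudely, the minority group appears *more* likely to receive care (+3.75
percentage points); after balancing health status within SES subgroups —
but leaving both groups' SES distributions intact — the ATT disparity
reverses to −6.06 percentage points: among subjects with the minority
group's case-mix, minority subjects are less likely to receive the
outcome. The concordance report verifies that the weights actually meet
the IOM requirement, while the undivided stratum-specific ("SSHS")
weights do not:

```r
rep <- concordance_report(d, list(
  deweight = w,
  sshs = disparity_weights(d, estimand = "att", method = "sshs_ps")
))
attr(rep, "concordance")
#> # A tibble: 2 × 6
#>   weight_set method      estimand n_flagged max_value iom_concordant
#> 1 deweight   deweighting att              0  9.83e-11 TRUE
#> 2 sshs       sshs_ps     att              2  2.99e- 1 FALSE
```

Every $D_1$ is exactly 0 (ATT deweighting leaves minority weights at 1),
every $D_0$ is at solver tolerance (the per-stratum CBPS balance equations
pin each subgroup's majority weight mass to its count), and all
within-subgroup health ASMDs $D_r$ sit near machine precision.

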