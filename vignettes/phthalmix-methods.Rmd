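---
title: "Methods: a Bayesian joint model for prenatal phthalate mixtures and childhood fat mass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Bayesian joint model for prenatal phthalate mixtures and childhood fat mass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Urinary phthalate metabolites measured in pregnancy are a standard set of
exposure biomarkers in environmental epidemiology.  Relating them to a
longitudinal childhood body-composition outcome raises four intertwined
statistical problems that `phthalmix` addresses in one joint Bayesian model:

1. **Censoring at the limit of detection (LOD).**  A fraction of
   concentrations fall below the assay LOD and are only known to lie below
   it.
2. **Correlated exposures.**  Metabolites share parent compounds and source
   products; unpenalized multi-exposure regressions are unstable and
   mutually confounded.
3. **Missing covariates.**  A handful of adjustment variables (last
   pregnancy weight, breastfeeding, child physical activity) are missing
   for some participants.
4. **Loss to follow-up.**  Children missing body-composition visits may
   differ systematically — possibly in the outcome itself, a missing-not-
   at-random (MNAR) mechanism that ignorable methods cannot address.

## The outcome model

For child $i$ at visit $j$, percent fat mass ($100 \times$ fat mass /
weight) is modelled as

$$y_{ij} = \mathbf{x}_{ij}'\boldsymbol\beta + b_i + \varepsilon_{ij},
\qquad b_i \sim N(0, \sigma_b^2), \quad
\varepsilon_{ij} \sim N(0, \sigma_e^2),$$

with a random intercept per child for the repeated measurements.  The fixed
effects comprise the exposures plus the adjustment set: child sex, age (and
sex × age), maternal race/ethnicity, education, work status, smoking,
breastfeeding, physical activity, maternal height, and polynomial terms in
maternal age (cubic), prepregnancy BMI (quadratic), gestational weight-gain
adequacy (cubic) and log creatinine (quadratic), plus calendar date of urine
collection.  Continuous covariates are standardized as $(x-\mu_x)/(2\sigma_x)$
so that one unit is a 2-SD change, comparable with a binary contrast;
exposures are standardized as $(\ln x - \mu)/\sigma$ so coefficients are per
SD of log concentration.

The four DEHP metabolites (MECPP, MEHHP, MEHP, MEOHP) are strongly
correlated because they share a parent compound, so they enter as a single
molar sum $\sum_k c_k / MW_k$ (µmol/L), recomputed at every MCMC iteration
from the current (partly imputed) component values.

### Priors and the precision convention

All coefficient priors are null-centred normals parameterized by a
*precision* $\tau$, i.e. variance $1/\tau$:

* exposures: $\tau = 1/16$, so the 95% prior interval is
  $\pm 1.96\sqrt{16} = \pm 7.84$, about one marginal SD of percent fat
  mass (≈ 8.4) — a weakly informative shrinkage prior that stabilises the
  correlated multi-exposure model;
* covariates: $\tau = 1/64$ ($\pm 15.7$, about two outcome SDs), including
  the intercept;
* imputation-submodel coefficients: $\tau = 1$, an odds-ratio range of
  0.14–7.1 for the logistic submodels;
* selection-model coefficients: $\tau = 2$, an odds-ratio range of 0.25–4.

This variance $= 1/\tau$ convention is pinned down by back-calculation: it
is the only reading under which all four calibration intervals above come
out at their stated widths simultaneously (e.g. $\tau = 2$ gives
$\exp(\pm 1.96/\sqrt 2) = (0.25, 4.0)$, while a variance $= 1/\tau^2$
reading would give $(0.38, 2.7)$).  `prior_interval()` exposes the
computation.

Two deliberate exceptions: the *selection-model intercept* receives a vague
prior (precision 0.01).  It is the baseline missingness log-odds — a
quantity far from zero whenever most potential visits are unobserved — and
shrinking it toward zero forces compensation through the outcome-dependence
coefficient $\gamma_y$, biasing exactly the parameter the sensitivity
analysis exists to estimate.  Variances ($\sigma_e^2$, $\sigma_b^2$, and the
submodel variances) get vague conjugate inverse-gamma(0.001, 0.001) priors,
the classic WinBUGS-era convention.

## Below-LOD imputation

At each sweep, every censored log concentration is redrawn from
$N(\mu_{\ln}, \sigma_{\ln}^2)$ truncated above at $\ln(\text{LOD})$, where
$(\mu_{\ln}, \sigma_{\ln})$ are the mean and SD of the *observed*
(above-LOD) log distribution of that metabolite, computed once and frozen.
The truncation is applied on the concentration scale — the natural lower
bound of zero is automatic for a lognormal, and an upper bound at the LOD is
exactly the censoring constraint.  Sampling uses the inverse-CDF method on
the log-probability scale (`rtnorm_upper()`), which stays accurate even
when the bound lies far in the lower tail; a rejection sampler serves as
the independent oracle in the tests.

Analytical correction factors (MBzP 0.72, MEP 0.66) are applied to both
concentrations and LODs before anything else, so correction commutes with
every later LOD-based step.  Mothers with urinary creatinine below
10 mg/dL are excluded as too dilute for reliable biomarker measurement.
For descriptive tables only, censored values are replaced by
LOD$/\sqrt{2}$, the standard convention for low censoring rates.

### Frozen standardization constants

Exposure standardization constants are computed once from the
LOD$/\sqrt 2$-completed analysis sample and frozen before MCMC, rather than
recomputed from imputed values at each iteration.  This keeps the design
matrix scale stable (a drifting standardization would entangle coefficient
and imputation updates) and makes results exactly reproducible; with the
low censoring rates here (≤ 8% for MEHP, ≤ 2% elsewhere) the difference is
negligible.

### Tertile coding

Dose-response models replace the standardized log concentration by
indicators for the 2nd and 3rd tertile of the *creatinine-corrected*
concentration (µg/g, or µmol/g for the DEHP sum), with cut points at the
1/3 and 2/3 type-7 empirical quantiles of the analysis sample and boundary
values assigned to the lower tertile (a deterministic tie rule).  Because
these models adjust for dilution through the correction itself, log
creatinine is dropped from the covariate set, and requesting it is a
configuration error.  Tertile assignments are frozen: censored values sit
below the LOD and therefore below any realistic cut point, so per-iteration
reclassification cannot occur.

## Covariate imputation inside the MCMC

Three submodels run inside the sampler, each with $\tau = 1$ coefficient
priors:

* **Last pregnancy weight** (normal linear model given education,
  race/ethnicity, child sex, smoking, work status, maternal age, birth
  weight, maternal height, gestational age, first pregnancy weight,
  prepregnancy BMI).  Gestational weight-gain adequacy — observed gain over
  IOM-style expected gain × 100 — is recalculated from each imputed weight,
  and its cubic design columns refresh immediately.
* **Breastfeeding** (logistic).
* **Physical activity** (logistic mixed model with child random
  intercepts, since activity is reported per visit).

Imputation is fully Bayesian: the full conditional of each imputed value
includes the outcome likelihood (and the selection likelihood under MNAR),
not just the submodel.  Binary values are drawn from their exact Bernoulli
full conditionals; the continuous weight uses a Metropolis step whose
independence proposal is the submodel itself, so the acceptance ratio
reduces to the outcome-likelihood ratio.

## The selection model for loss to follow-up

Under MNAR, every potential visit row of every child with measured
exposures enters the model, and a logistic regression for the missingness
indicator is fitted jointly:

$$\mathrm{logit}\, P(M_{ij} = 1) = \gamma_0 + \gamma_y\, y_{ij} +
\mathbf{z}_{ij}'\boldsymbol\gamma,$$

where $y_{ij}$ is the possibly *unobserved* percent fat mass, entering in
its natural units so $\exp(\gamma_y)$ is the odds ratio of missingness per
1% fat mass.  Missing outcomes are latent variables updated by a
Metropolis step proposing from their Gaussian full conditional under the
outcome model and accepting on the logistic tilt; the $\gamma$ block uses a
random-walk proposal preconditioned by a classical logistic fit.  Because
$\gamma$ and the latent outcomes are strongly coupled, each sweep performs
a few extra inner updates of this pair — they cost little next to the
conjugate blocks and substantially improve mixing.  Children entirely
absent from follow-up contribute rows at the visit-schedule mean ages.
Intermittent missingness and terminal dropout share one model.

Setting $\gamma_y = 0$ (`selection_spec(fix_gamma_y = 0)`) makes the
mechanism ignorable; the tests verify that the exposure-coefficient
posteriors then coincide with the MAR fit's.

## Sampler design

One sweep updates, in order: censored log concentrations (fixed truncated
normals, then DEHP sum recomputation), imputed covariates, submodel
coefficients (conjugate for the normal submodel, preconditioned
random-walk Metropolis for the logistic ones, per-child random-walk
updates for the activity intercepts), the selection block under MNAR, then
the conjugate blocks: fixed effects (multivariate normal), random
intercepts, and inverse-gamma variances.  Metropolis proposal scales are
frozen at initialization (from classical warm-start fits), never adapted
afterwards, so the chain's stationary distribution is exact.  Input rows
are sorted to a canonical (subject, visit) order before any random draw,
making results bit-identical under permutations of the input files.

Chains are summarized by equal-tailed percentile intervals (95% and 80%);
the 80% interval drives the effect-modification flag for sex × exposure
product terms.  Convergence reporting uses rank-normalized split R-hat
(with the classic Gelman–Rubin value alongside) and autocorrelation-
truncated effective sample sizes; the convergence gate used in the
package's own sensitivity harness is R-hat < 1.05.

## What the synthetic cohort emulates

`truth_config()` fixes the generating process to the study conditions the
package targets:

* 180 children (380 for the loss-to-follow-up analysis), three visits
  scheduled at mean ages 4.9, 6.1 and 7.8 years with SDs 0.4, 0.2 and 0.8;
* log-normal metabolite concentrations with geometric means anchored to
  the observed third-trimester distributions; log-SDs taken from the
  observed interquartile ranges, except MEHP — the one metabolite with
  material censoring — whose log-SD (1.388) is calibrated so that 8.3% of
  draws fall below its LOD of 0.9 µg/L;
* within-DEHP log-scale correlations of 0.9, 0.4 between other pairs;
* an outcome process with marginal mean ≈ 18.4% and SD ≈ 8.4%
  ($\sigma_b = 6$, $\sigma_e = 4$, age slope ≈ 3.1%/yr for girls with a
  −2.0%/yr sex × age interaction, sexes crossing near age 7.5);
* covariate missingness at the observed rates (12% of last pregnancy
  weights, one breastfeeding report, a few whole children's activity
  reports);
* dropout: MCAR at rate 1/3 by default (about two observed visits per
  child, matching the primary-analysis condition), or MNAR with
  $\gamma_y = \ln(0.81)$ per 1% fat mass and an intercept of 4.63 chosen
  so that roughly a third of potential visits are observed.

Features of real data it does **not** emulate: measurement error in the
bioimpedance equations, secular exposure trends, within-pregnancy
variability of spot-urine concentrations, and clustering of dropout beyond
what the outcome and covariates induce.  Passing tests therefore
demonstrate statistical correctness of the machinery under the assumed
model, not robustness to these violations.

Three RNG streams (mothers / visits / dropout) are split from the master
seed, so toggling the dropout mechanism leaves the exposures untouched.

## Validation problem sizes

The test suite exercises the full pipeline at the sizes the package's
validation design specifies: the OLS-equivalence check runs one 200-child
cohort for 20,000 sweeps with flat priors and no random intercepts; the
recovery study fits 20 replicate 180-child cohorts (truth
$\beta_{\Sigma DEHP} = -0.89$) with 2,000 burn-in + 8,000 kept sweeps,
requiring absolute mean bias below 0.3 and ≥ 16/20 interval coverage; the
selection-model study fits 10 MNAR and 10 MCAR replicates of 380-child
cohorts with 600 + 3,000 sweeps, requiring the mean recovered odds ratio
within ±0.05 of 0.81 and null coverage in ≥ 9/10.  Production analyses
should use the defaults (10,000 burn-in, 50,000 iterations, 2 chains; 10
chains for the selection model), which the `mcmc` settings control.

## Known limitations

* The truncated-normal imputation uses frozen marginal moments per
  metabolite; it ignores both the outcome and the cross-metabolite
  correlation when re-imputing censored cells.  This mirrors the intended
  procedure and is innocuous at these censoring rates, but would
  understate uncertainty if large fractions were censored.
* The logistic submodels use Metropolis updates rather than exact
  augmentation; mixing is monitored via the reported acceptance rates and
  R-hat.
* Selection models are inherently sensitive to the assumed missingness
  structure; `selection_spec(covariates = ...)` exists precisely to vary
  it, and conclusions should be reported across such variations.
* BMI z-scores require a user-supplied LMS reference table; the bundled
  `lms_synthetic.csv` is a smooth synthetic stand-in for testing, not a
  population reference.
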