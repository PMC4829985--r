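# phthalmix

Bayesian joint modelling of prenatal urinary phthalate metabolite mixtures
and repeated childhood percent fat mass measurements.

## The problem

Cohort studies of prenatal chemical exposures and child body composition
face four coupled statistical problems: biomarker concentrations censored
below the assay limit of detection (LOD); strongly correlated exposures
(metabolites of the same parent phthalate) that destabilise multi-exposure
regressions; sporadically missing covariates; and loss to follow-up that
may depend on the unmeasured outcome itself.  `phthalmix` addresses all
four in a single Gibbs sampler, for epidemiologists and biostatisticians
analysing this class of longitudinal exposure-outcome data — and ships a
synthetic-cohort generator with known ground truth so the whole pipeline
is testable without access to any cohort's raw data.

## The model

Percent fat mass for child $i$ at visit $j$:

$$y_{ij} = \mathbf{x}_{ij}'\boldsymbol\beta + b_i + \varepsilon_{ij},
\qquad b_i \sim N(0,\sigma_b^2),\quad \varepsilon_{ij} \sim N(0,\sigma_e^2)$$

* **Exposures**: standardized natural-log urinary concentrations (per-SD
  coefficients), with the four DEHP metabolites entering as a molar sum
  recomputed at every MCMC iteration; or creatinine-corrected tertile
  indicators for dose-response.
* **Shrinkage priors**: null-centred normals with precision $\tau$
  (variance $1/\tau$): $\tau = 1/16$ for exposures, $1/64$ for covariates,
  $1$ for imputation submodels, $2$ for selection-model coefficients.
* **Below-LOD imputation**: censored log concentrations redrawn each sweep
  from $N(\mu_{\ln}, \sigma_{\ln}^2)$ truncated above at $\ln$ LOD, with
  frozen moments from the observed distribution.
* **Covariate imputation**: three submodels (normal for last pregnancy
  weight, from which gestational weight-gain adequacy is recalculated;
  logistic for breastfeeding; logistic mixed for visit-level physical
  activity) run inside the MCMC with full outcome feedback.
* **MNAR selection model**: jointly with the outcome model, a logistic
  regression for the missingness of each potential visit's outcome,
  $\mathrm{logit}\,P(M_{ij}{=}1) = \gamma_0 + \gamma_y y_{ij} +
  \mathbf z_{ij}'\boldsymbol\gamma$, where $y_{ij}$ may itself be
  unobserved; $\exp(\gamma_y)$ is the odds ratio of missingness per 1%
  fat mass.

See `vignettes/phthalmix-methods.Rmd` for assumptions, numerical choices
and limitations.

## Worked example

Simulate a 180-child cohort at the package's default study conditions with
a true DEHP-sum effect of −0.89% fat mass per SD of log concentration,
then fit the multiple-metabolite model:

```r
library(phthalmix)

cfg <- truth_config(beta_exposure = c(MEP = 0, MnBP = 0, MiBP = 0,
                                      MCPP = 0, MBzP = 0, SumDEHP = -0.89))
cohort <- simulate_cohort(cfg, seed = 101)

fit <- phthalmix_fit(cohort$mothers, cohort$visits,
                     model_spec(mcmc = list(burn_in = 2000,
                                            iterations = 8000,
                                            chains = 1, seed = 1)))
print(fit)
```

```
Bayesian phthalate-mixture fat-mass model
  exposures: MEP, MnBP, MiBP, MCPP, MBzP, SumDEHP [continuous coding]
  interaction: none   missingness: MAR
  children: 171   modeled visit rows: 363  ( 363 observed )
  chains: 1  retained draws/chain: 8000

Exposure effects (per SD ln concentration or tertile contrast):
 parameter estimate          ci95
       MEP     0.49 (-0.84, 1.80)
      MnBP    -0.58 (-1.93, 0.75)
      MiBP    -0.44 (-1.85, 0.95)
      MCPP     0.95 (-0.41, 2.31)
      MBzP    -0.24 (-1.49, 1.02)
   SumDEHP    -0.51 (-1.77, 0.77)
```

Reading the output: each exposure row is the posterior mean difference in
percent fat mass per SD increase in log concentration, with its 95%
credible interval.  The SumDEHP estimate recovers the simulated −0.89
within its interval; the null metabolites straddle zero.  `summary(fit)`
adds 80% intervals, split R-hat, effective sample sizes and the
sex-interaction heterogeneity flag; `plot(fit)` draws the forest plot.

The loss-to-follow-up sensitivity analysis over the full 380-child cohort:

```r
cfg5 <- truth_config(n_children = 380L, dropout = list(mechanism = "MNAR"))
cohort5 <- simulate_cohort(cfg5, seed = 201)
sel <- fit_selection(cohort5$mothers, cohort5$visits,
                     model_spec(missingness = "MNAR",
                                mcmc = list(burn_in = 600,
                                            iterations = 3000, seed = 1)),
                     selection = selection_spec(chains = 1))
dropout_or(sel)
```

```
        or ci95_lower ci95_upper
     0.826      0.792      0.858
```

The simulated mechanism removed visits with odds multiplied by 0.81 per 1%
fat mass; the fitted odds ratio recovers it.

An end-to-end run (simulation → descriptive table → fits → report tables →
manifest) is one call:

```r
run_pipeline(list(simulate = list(seed = 3),
                  paths = list(outdir = "run"),
                  fits = list(tertile = TRUE, interaction = TRUE)))
```

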