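test_that("generation is deterministic and sectioned by RNG stream", {
  a <- simulate_cohort(truth_config(n_children = 30L), seed = 17)
  b <- simulate_cohort(truth_config(n_children = 30L), seed = 17)
  expect_identical(a$mothers, b$mothers)
  expect_identical(a$visits, b$visits)

  # toggling the dropout mechanism must not perturb the exposures
  c2 <- simulate_cohort(truth_config(
    n_children = 30L, dropout = list(mechanism = "MCAR", mcar_rate = 0.5)),
    seed = 17)
  expect_identical(a$mothers, c2$mothers)
})

test_that("MEHP censoring matches its calibrated below-LOD rate", {
  co <- quick_cohort(n = 180, seed = 21)
  frac <- mean(co$mothers$cens_MEHP)
  p <- 0.083
  se <- sqrt(p * (1 - p) / 180)
  expect_lt(abs(frac - p), 3 * se)
  # every metabolite detected in > 90% of samples
  for (code in default_registry()$code)
    expect_gt(mean(!co$mothers[[paste0("cens_", code)]]), 0.90)
})

test_that("censored fractions converge to the normal-CDF prediction", {
  cfg <- truth_config(n_children = 50000L)
  m <- simulate_mothers(cfg, seed = 8)
  reg <- cfg$registry
  for (code in c("MEHP", "MiBP")) {
    lod_c <- reg$lod[reg$code == code] *
      reg$correction_factor[reg$code == code]
    p <- pnorm((log(lod_c) - cfg$exposure_log_mean[[code]]) /
                 cfg$exposure_log_sd[[code]])
    frac <- mean(m[[paste0("cens_", code)]])
    expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 50000) + 1e-6)
  }
})

test_that("exposure correlation structure is controllable", {
  co <- quick_cohort(n = 180, seed = 5)
  ln <- attr(co$mothers, "ln_conc_true")
  dehp <- c("MECPP", "MEHHP", "MEHP", "MEOHP")
  r_within <- cor(ln[, dehp])
  expect_true(all(r_within[upper.tri(r_within)] > 0.8))

  co0 <- simulate_cohort(truth_config(
    n_children = 180L, corr_within_dehp = 0, corr_between = 0), seed = 5)
  ln0 <- attr(co0$mothers, "ln_conc_true")
  r0 <- cor(ln0[, dehp])
  expect_true(all(abs(r0[upper.tri(r0)]) < 0.25))
})

test_that("the outcome process matches its configured moments", {
  co <- quick_cohort(n = 400, seed = 6,
                     dropout = list(mechanism = "MCAR", mcar_rate = 0))
  y <- 100 * co$visits$fat_mass / co$visits$weight
  expect_lt(abs(mean(y) - 18.4), 1.2)
  expect_gt(sd(y), 7.2); expect_lt(sd(y), 8.8)

  # null exposure effects -> near-zero exposure-outcome correlation
  z <- attr(co$mothers, "ln_conc_true")
  ybar <- tapply(y, co$visits$subject_id, mean)[co$mothers$subject_id]
  for (code in c("MEP", "MEHP"))
    expect_lt(abs(cor(z[, code], ybar)), 0.15)

  # sigma_b = 0 kills the within-child correlation of residuals
  co0 <- simulate_cohort(truth_config(
    n_children = 300L, sigma_b = 0,
    dropout = list(mechanism = "MCAR", mcar_rate = 0)), seed = 9)
  y0 <- 100 * co0$visits$fat_mass / co0$visits$weight
  moth0 <- co0$mothers[match(co0$visits$subject_id,
                             co0$mothers$subject_id), ]
  r0 <- stats::resid(stats::lm(
    y0 ~ co0$visits$age_months * moth0$child_sex + moth0$prepreg_bmi +
      moth0$smoking + attr(co0$mothers, "breastfed_true")[match(
        co0$visits$subject_id, co0$mothers$subject_id)]))
  m <- matrix(r0, ncol = 3, byrow = TRUE)   # rows ordered by (child, visit)
  expect_lt(abs(cor(m[, 1], m[, 2])), 0.15)
})

test_that("dropout mechanisms behave as configured", {
  # MCAR at rate 0.2
  co <- simulate_cohort(truth_config(
    n_children = 400L, dropout = list(mechanism = "MCAR", mcar_rate = 0.2)),
    seed = 3)
  frac <- mean(co$visits$outcome_missing)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / nrow(co$visits)))

  # effectively -infinity intercept -> no missingness
  co_none <- simulate_cohort(truth_config(
    n_children = 100L,
    dropout = list(mechanism = "MNAR", gamma0 = -30, gamma_y = 0)), seed = 3)
  expect_equal(sum(co_none$visits$outcome_missing), 0)

  # MNAR with gamma_y < 0: children with more fat mass are retained,
  # biasing the observed mean upward
  co_mnar <- simulate_cohort(truth_config(
    n_children = 600L, dropout = list(mechanism = "MNAR")), seed = 13)
  tr <- co_mnar$truth$dropout
  y_all <- tr$y_all
  y_obs <- y_all[co_mnar$visits$outcome_missing == 0]
  expect_gt(mean(y_obs), mean(y_all))
})

test_that("a logistic-fit oracle recovers the MNAR dropout odds ratio", {
  co <- simulate_cohort(truth_config(
    n_children = 1700L, dropout = list(mechanism = "MNAR")), seed = 31)
  tr <- co_truth <- co$truth$dropout
  fit <- glm(co$visits$outcome_missing ~ co_truth$y_all,
             family = binomial())
  est <- coef(fit)[2]
  se <- sqrt(diag(vcov(fit)))[2]
  expect_lt(abs(est - log(0.81)), 3 * se)
})
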