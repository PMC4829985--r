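# Design construction and Gibbs-sampler component checks.

test_that("the design matrix has the prescribed columns per mode", {
  co <- quick_cohort(n = 50, seed = 2)
  ctx <- prepare_model_data(co$mothers, co$visits, model_spec())
  ci <- ctx$col_info
  expect_equal(length(ci$exposure), 6)      # 5 metabolites + SumDEHP
  expect_true(all(c("lncreat_std", "lncreat_std2", "date_std",
                    "sex:age_std") %in% colnames(ctx$X)))
  expect_equal(sum(grepl("^mat_age_std", colnames(ctx$X))), 3)  # cubic
  expect_equal(sum(grepl("^ppbmi_std", colnames(ctx$X))), 2)    # quadratic
  expect_equal(sum(grepl("^gwg_std", colnames(ctx$X))), 3)      # cubic
  # shrinkage precisions attached per group
  expect_equal(unname(ci$prior_prec["SumDEHP"]), 1 / 16)
  expect_equal(unname(ci$prior_prec["smoking"]), 1 / 64)

  # tertile mode: two indicators per exposure, no creatinine terms
  ctxt <- prepare_model_data(co$mothers, co$visits,
                             model_spec(exposure_coding = "tertile"))
  expect_equal(length(ctxt$col_info$exposure), 12)
  expect_false(any(grepl("lncreat", colnames(ctxt$X))))
  expect_error(model_spec(exposure_coding = "tertile",
                          include_creatinine = TRUE), "config error")

  # interaction mode adds one product per exposure plus sex x ln creatinine
  ctxi <- prepare_model_data(co$mothers, co$visits,
                             model_spec(interaction = "sex"))
  expect_equal(ncol(ctxi$X), ncol(ctx$X) + 6 + 1)
  expect_equal(length(ctxi$col_info$heterogeneity), 6)
  expect_equal(unname(ctxi$col_info$prior_prec["sex:SumDEHP"]), 1 / 16)
  expect_equal(unname(ctxi$col_info$prior_prec["sex:lncreat_std"]), 1 / 64)
})

test_that("exposure standardization inside the design is frozen and exact", {
  co <- quick_cohort(n = 60, seed = 7)
  ctx <- prepare_model_data(co$mothers, co$visits, model_spec())
  E <- exposure_scores(ctx, ctx$ln_conc0)
  expect_equal(colMeans(E), setNames(rep(0, 6), colnames(E)),
               tolerance = 1e-10)
  expect_equal(apply(E, 2, sd), setNames(rep(1, 6), colnames(E)),
               tolerance = 1e-10)
})

test_that("log_joint reproduces an independently assembled density", {
  co <- quick_cohort(n = 25, seed = 3)
  spec <- quick_spec()
  ctx <- prepare_model_data(co$mothers, co$visits, spec)
  set.seed(1)
  st <- init_state(ctx)
  lj <- log_joint(st, ctx)
  expect_true(is.finite(lj))

  # outcome component: direct Gaussian recomputation
  mu <- as.numeric(st$X %*% st$beta) + st$b[ctx$row_child]
  outcome <- sum(dnorm(ctx$y, mu, sqrt(st$sig2_e), log = TRUE))
  # shifting all outcomes shifts only the outcome term
  st2 <- init_state(ctx)
  st2$y <- st$y + 1
  mu2 <- as.numeric(st2$X %*% st2$beta) + st2$b[ctx$row_child]
  outcome2 <- sum(dnorm(st2$y, mu2, sqrt(st2$sig2_e), log = TRUE))
  expect_equal(log_joint(st2, ctx) - lj, outcome2 - outcome,
               tolerance = 1e-8)

  # exposure-coefficient perturbation: analytic prior + likelihood change
  delta <- 0.3
  j <- which(names(st$beta) == "SumDEHP")
  tau <- spec$tau_exposure
  st3 <- init_state(ctx)
  st3$beta[j] <- st3$beta[j] + delta
  prior_change <- -tau * (st$beta[j] * delta + delta^2 / 2)
  mu3 <- as.numeric(st3$X %*% st3$beta) + st3$b[ctx$row_child]
  lik_change <- sum(dnorm(ctx$y, mu3, sqrt(st$sig2_e), log = TRUE)) - outcome
  expect_equal(log_joint(st3, ctx) - lj,
               unname(prior_change + lik_change), tolerance = 1e-8)

  # support violation: censored cell above its LOD bound
  st4 <- init_state(ctx)
  code <- names(ctx$cens_info)[1]
  st4$ln_conc[ctx$cens_info[[code]]$idx[1], code] <-
    ctx$cens_info[[code]]$bound + 0.5
  expect_equal(log_joint(st4, ctx), -Inf)
})

test_that("truncated-normal imputation respects its support and oracle", {
  set.seed(42)
  x <- rtnorm_upper(10000, mean = 1.5, sd = 1.2, upper = log(0.9))
  expect_true(all(x <= log(0.9)))
  oracle <- rtnorm_reject(40000, 1.5, 1.2, log(0.9))
  ks <- suppressWarnings(ks.test(x, oracle))$statistic
  expect_lt(unname(ks), 0.02)

  # untruncated limit: moments recover the parent normal
  y <- rtnorm_upper(40000, 2, 0.7, upper = Inf)
  expect_lt(abs(mean(y) - 2), 0.02)
  expect_lt(abs(sd(y) - 0.7), 0.02)

  # far-tail truncation stays finite and in support
  z <- rtnorm_upper(1000, 0, 1, upper = -8)
  expect_true(all(is.finite(z)) && all(z <= -8))
})

test_that("impute_censored redraws only censored cells below the bound", {
  co <- quick_cohort(n = 120, seed = 11)
  ctx <- prepare_model_data(co$mothers, co$visits, model_spec())
  set.seed(2)
  st <- init_state(ctx)
  before <- st$ln_conc
  impute_censored(st, ctx)
  for (code in names(ctx$cens_info)) {
    ci <- ctx$cens_info[[code]]
    expect_true(all(st$ln_conc[ci$idx, code] <= ci$bound))
    obs_rows <- setdiff(seq_len(ctx$n_child), ci$idx)
    expect_identical(st$ln_conc[obs_rows, code], before[obs_rows, code])
  }
  # the SumDEHP design column tracks the imputed components
  E <- exposure_scores(ctx, st$ln_conc)
  expect_equal(st$X[, "SumDEHP"], E[ctx$row_child, "SumDEHP"])
})

test_that("covariate imputation leaves complete data untouched", {
  co <- quick_cohort(n = 40, seed = 5, miss_last_weight = 0,
                     miss_breastfed = 0, miss_activity_child = 0)
  ctx <- prepare_model_data(co$mothers, co$visits, model_spec())
  expect_equal(length(ctx$W_missing), 0)
  set.seed(3)
  st <- init_state(ctx)
  W0 <- st$W; B0 <- st$B; A0 <- st$A
  impute_covariates(st, ctx)
  expect_identical(st$W, W0)
  expect_identical(st$B, B0)
  expect_identical(st$A, A0)
})

test_that("fixed seeds give bit-identical chains and permutation stability", {
  co <- quick_cohort(n = 40, seed = 19)
  spec <- quick_spec(burn = 50, iters = 150)
  f1 <- phthalmix_fit(co$mothers, co$visits, spec)
  f2 <- phthalmix_fit(co$mothers, co$visits, spec)
  expect_identical(f1$chains$draws, f2$chains$draws)

  # permuting input row order must not change anything (canonical keying)
  set.seed(4)
  mp <- co$mothers[sample.int(nrow(co$mothers)), ]
  for (a in c("ln_conc_true", "breastfed_true", "last_preg_weight_true"))
    attr(mp, a) <- attr(co$mothers, a)
  vp <- co$visits[sample.int(nrow(co$visits)), ]
  f3 <- phthalmix_fit(mp, vp, spec)
  expect_identical(f1$chains$draws, f3$chains$draws)
})

test_that("prior-only draws reproduce the precision convention", {
  co <- quick_cohort(n = 30, seed = 23)
  spec <- model_spec(mcmc = list(iterations = 20000L, seed = 9))
  pf <- phthalmix_fit(co$mothers, co$visits, spec, prior_only = TRUE)
  s <- summary(pf)
  expect_equal(s$sd[s$parameter == "SumDEHP"], 4, tolerance = 0.02)
  expect_equal(s$sd[s$parameter == "smoking"], 8, tolerance = 0.02)
})

test_that("increasing the exposure precision shrinks estimates toward zero", {
  cfg <- truth_config(
    n_children = 120L,
    beta_exposure = c(MEP = 0, MnBP = 0, MiBP = 0, MCPP = 0, MBzP = 0,
                      SumDEHP = -3))
  co <- simulate_cohort(cfg, seed = 3)
  post_mean <- vapply(c(1 / 64, 1 / 16, 1), function(tau) {
    spec <- model_spec(tau_exposure = tau,
                       mcmc = list(burn_in = 300, iterations = 1500,
                                   chains = 1, seed = 5))
    f <- phthalmix_fit(co$mothers, co$visits, spec)
    s <- summary(f)
    s$mean[s$parameter == "SumDEHP"]
  }, numeric(1))
  expect_gt(abs(post_mean[1]), abs(post_mean[2]) - 0.05)
  expect_gt(abs(post_mean[2]), abs(post_mean[3]) + 0.1)
  expect_true(all(post_mean < 0))
})

test_that("single- and multiple-exposure fits agree when exposures are independent", {
  cfg <- truth_config(
    n_children = 150L, corr_within_dehp = 0.9, corr_between = 0,
    beta_exposure = c(MEP = 0, MnBP = 0, MiBP = 0, MCPP = 0, MBzP = 0,
                      SumDEHP = -2))
  co <- simulate_cohort(cfg, seed = 8)
  fit_multi <- phthalmix_fit(co$mothers, co$visits,
                             quick_spec(burn = 400, iters = 1600, seed = 2))
  fit_single <- phthalmix_fit(co$mothers, co$visits,
                              quick_spec(burn = 400, iters = 1600, seed = 3,
                                         exposures = "SumDEHP"))
  sm <- summary(fit_multi); ss <- summary(fit_single)
  m1 <- sm$mean[sm$parameter == "SumDEHP"]
  m2 <- ss$mean[ss$parameter == "SumDEHP"]
  mcse <- sqrt(sm$sd[sm$parameter == "SumDEHP"]^2 /
                 sm$ess[sm$parameter == "SumDEHP"] +
               ss$sd[ss$parameter == "SumDEHP"]^2 /
                 ss$ess[ss$parameter == "SumDEHP"])
  expect_lt(abs(m1 - m2), max(4 * mcse, 0.25))
})

test_that("the mixed-model posterior matches an independent JAGS fit", {
  # complete data (no censoring, no missing covariates): the model reduces
  # to a shrinkage-prior random-intercept LMM that JAGS can fit exactly
  lm_means <- truth_config()$exposure_log_mean
  lm_means["MEHP"] <- lm_means["MEHP"] + 2.5
  cfg <- truth_config(
    n_children = 70L, exposure_log_mean = lm_means,
    beta_exposure = c(MEP = 0, MnBP = 0, MiBP = 0, MCPP = 0, MBzP = 0,
                      SumDEHP = -2),
    miss_last_weight = 0, miss_breastfed = 0, miss_activity_child = 0)
  co <- simulate_cohort(cfg, seed = 3)
  fit <- phthalmix_fit(co$mothers, co$visits,
                       quick_spec(burn = 500, iters = 2500, seed = 2))
  ctx <- fit$ctx
  library(rjags)
  jm <- "model {
    for (r in 1:N) { y[r] ~ dnorm(inprod(X[r,], beta) + b[child[r]], tau_e) }
    for (i in 1:n) { b[i] ~ dnorm(0, tau_b) }
    for (j in 1:p) { beta[j] ~ dnorm(0, prec[j]) }
    tau_e ~ dgamma(0.001, 0.001)
    tau_b ~ dgamma(0.001, 0.001)
  }"
  dat <- list(y = ctx$y, X = ctx$X, child = ctx$row_child, N = ctx$N,
              n = ctx$n_child, p = ncol(ctx$X),
              prec = unname(ctx$col_info$prior_prec))
  jmod <- jags.model(textConnection(jm), data = dat, n.chains = 1,
                     quiet = TRUE,
                     inits = list(.RNG.name = "base::Mersenne-Twister",
                                  .RNG.seed = 7))
  update(jmod, 1000, progress.bar = "none")
  samp <- coda.samples(jmod, "beta", 3000, progress.bar = "none")[[1]]
  s <- summary(fit)
  for (par in c("SumDEHP", "sex", "smoking")) {
    j <- which(colnames(ctx$X) == par)
    i <- s$parameter == par
    mcse <- sqrt(s$sd[i]^2 / s$ess[i] + var(samp[, j]) / 500)
    expect_lt(abs(s$mean[i] - mean(samp[, j])), 4 * mcse)
    expect_lt(abs(s$sd[i] - sd(samp[, j])) / s$sd[i], 0.15)
  }
})

test_that("resume from a checkpoint reproduces the uninterrupted chain", {
  co <- quick_cohort(n = 30, seed = 29)
  f_short <- phthalmix_fit(co$mothers, co$visits,
                           quick_spec(burn = 50, iters = 100, seed = 3))
  ext <- resume_fit(f_short, 150)
  f_long <- phthalmix_fit(co$mothers, co$visits,
                          quick_spec(burn = 50, iters = 250, seed = 3))
  expect_identical(rbind(f_short$chains$draws[[1]], ext$draws[[1]]),
                   f_long$chains$draws[[1]])
})

test_that("fit methods expose coefficients, fits, residuals and simulations", {
  co <- quick_cohort(n = 40, seed = 31)
  fit <- phthalmix_fit(co$mothers, co$visits,
                       quick_spec(burn = 100, iters = 300))
  cf <- coef(fit)
  expect_named(cf)
  expect_true("SumDEHP" %in% names(cf))
  fv <- fitted(fit)
  expect_equal(length(fv), fit$ctx$N)
  rs <- residuals(fit)
  expect_equal(length(rs), sum(fit$ctx$obs))
  expect_lt(mean(abs(rs)), 10)
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(fit$ctx$N, 3))
  expect_output(print(fit), "Exposure effects")
  expect_s3_class(summary(fit), "summary.phthalmix_fit")
})
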