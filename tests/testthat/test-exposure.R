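test_that("correction factors scale concentrations and LODs", {
  m <- tiny_mothers()
  m$MBzP <- c(10, 5)
  m$MEP <- c(10, 5)
  out <- apply_correction_factors(m)
  expect_equal(out$MBzP, c(7.2, 3.6))        # factor 0.72
  expect_equal(out$MEP, c(6.6, 3.3))         # factor 0.66
  expect_equal(out$MnBP, m$MnBP)             # factor 1: identity
  lods <- attr(out, "lods")
  expect_equal(unname(lods["MEP"]), 0.39 * 0.66)     # 0.2574
  expect_equal(round(unname(lods["MEP"]), 2), 0.26)
  expect_equal(round(unname(lods["MBzP"]), 2), 0.08)
})

test_that("dilute-urine exclusion uses a strict 10 mg/dL threshold", {
  m <- tiny_mothers()
  m$creatinine <- c(9.9, 10.0)
  sp <- exclude_dilute(m)
  expect_equal(sp$excluded$subject_id, "A1")
  expect_equal(sp$kept$subject_id, "A2")
  m$creatinine <- c(50, 120)
  expect_equal(nrow(exclude_dilute(m)$excluded), 0)
})

test_that("LOD/sqrt(2) substitution touches only censored cells", {
  m <- tiny_mothers()
  m$cens_MEHP <- c(TRUE, FALSE)
  m$MEHP <- c(0.9, 2.0)
  out <- substitute_lod_sqrt2(apply_correction_factors(m))
  expect_equal(out$MEHP[1], 0.9 / sqrt(2), tolerance = 1e-12)
  expect_equal(round(out$MEHP[1], 5), 0.63640)
  expect_equal(out$MEHP[2], 2.0)
  # no censored cells -> identity
  m2 <- tiny_mothers()
  out2 <- substitute_lod_sqrt2(apply_correction_factors(m2))
  expect_equal(out2$MEHP, m2$MEHP)
})

test_that("correction factors commute with LOD/sqrt(2) substitution", {
  m <- tiny_mothers()
  m$cens_MEP <- c(TRUE, FALSE)
  m$MEP <- c(0.39, 4)
  a <- substitute_lod_sqrt2(apply_correction_factors(m))
  # substituting first (raw LOD/sqrt2), then correcting
  m2 <- m
  m2$MEP[1] <- 0.39 / sqrt(2)
  m2$cens_MEP <- c(FALSE, FALSE)
  b <- apply_correction_factors(m2)
  expect_equal(a$MEP, b$MEP, tolerance = 1e-12)
})

test_that("descriptive table matches closed-form oracles", {
  m <- tiny_mothers()
  m$MnBP <- c(1, 100)          # symmetric logs: GM = 10
  out <- substitute_lod_sqrt2(apply_correction_factors(m))
  tab <- descriptive_table(out)
  expect_equal(tab$geometric_mean[tab$metabolite == "MnBP"], 10)

  # censored + observed pair: GM = sqrt(LOD/sqrt(2) * x)
  m$cens_MEHP <- c(TRUE, FALSE)
  m$MEHP <- c(0.9, 2.0)
  tab2 <- descriptive_table(substitute_lod_sqrt2(apply_correction_factors(m)))
  gm <- tab2$geometric_mean[tab2$metabolite == "MEHP"]
  expect_equal(gm, sqrt(0.9 / sqrt(2) * 2), tolerance = 1e-12)
  expect_equal(round(gm, 5), 1.12818)
  expect_equal(tab2$percent_detected[tab2$metabolite == "MEHP"], 50)

  # percent detected on a realistic cohort: 2 censored of 180 -> 98.9
  expect_equal(round(100 * 178 / 180, 1), 98.9)

  # naive log-mean oracle on a fully observed column
  co <- quick_cohort(n = 80, seed = 4)
  comp <- substitute_lod_sqrt2(apply_correction_factors(co$mothers))
  tab3 <- descriptive_table(comp)
  expect_equal(tab3$geometric_mean[tab3$metabolite == "MnBP"],
               exp(mean(log(comp$MnBP))), tolerance = 1e-12)
  expect_true("SumDEHP" %in% tab3$metabolite)
})

test_that("DEHP molar sum follows unit algebra", {
  reg <- default_registry()
  codes <- c("MECPP", "MEHHP", "MEHP", "MEOHP")
  zeros <- setNames(rep(0, 4), codes)
  expect_equal(molar_sum_dehp(zeros), 0)
  mw <- setNames(reg$mol_weight, reg$code)[codes]
  expect_equal(molar_sum_dehp(mw), 4.0)          # ug/L over ug/umol = 1 each
  x <- setNames(c(30, 20, 6, 18), codes)
  expect_equal(molar_sum_dehp(2 * x), 2 * molar_sum_dehp(x))
  expect_equal(molar_sum_dehp(x[rev(codes)]), molar_sum_dehp(x))
  expect_error(molar_sum_dehp(x[1:3]), "missing component")
})

test_that("creatinine correction converts to per-gram units", {
  expect_equal(creatinine_correct(100, 100), 100)   # 100 mg/dL = 1 g/L
  expect_equal(creatinine_correct(50, 200), 25)
  expect_error(creatinine_correct(10, 0), "creatinine")
})

test_that("standardization is exact on its defining identities", {
  co <- quick_cohort(n = 50, seed = 9)
  comp <- substitute_lod_sqrt2(apply_correction_factors(co$mothers))
  cst <- exposure_constants(comp)
  z <- standardize_exposure(log(comp$MEP), cst, "MEP")
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  row <- cst$exposure[cst$exposure$code == "MEP", ]
  expect_equal(standardize_exposure(row$mean, cst, "MEP"), 0)
  expect_equal(standardize_exposure(row$mean + row$sd, cst, "MEP"), 1)

  expect_equal(standardize_covariate(5, 5, 2), 0)
  expect_equal(standardize_covariate(5 + 2 * 2, 5, 2), 1)  # 2-SD change
  expect_equal(standardize_covariate(7, 5, 2) - standardize_covariate(4, 5, 2),
               3 / (2 * 2))
})

test_that("tertiles cut at empirical thirds with ties going down", {
  t9 <- tertile_categorize(1:9)
  expect_equal(t9$category, c(1, 1, 1, 2, 2, 2, 3, 3, 3))
  expect_equal(t9$t2, as.numeric(t9$category == 2))

  # brute-force oracle for the boundary rule on small vectors
  for (seed in 1:5) {
    set.seed(seed)
    x <- sample(c(runif(7), rep(0.5, 2)))
    tt <- tertile_categorize(x)
    q <- quantile(x, c(1, 2) / 3, type = 7, names = FALSE)
    oracle <- vapply(x, function(v) {
      if (v <= q[1]) 1L else if (v <= q[2]) 2L else 3L
    }, integer(1))
    expect_equal(tt$category, oracle)
  }
  # a value exactly at a cut point goes to the lower tertile
  x <- c(1, 2, 3, 4, 5, 6)
  q1 <- quantile(x, 1 / 3, type = 7, names = FALSE)
  tt <- tertile_categorize(c(x, q1))
  expect_equal(tt$category[7], 1L)

  expect_error(tertile_categorize(rep(2, 10)), "degenerate")
})

test_that("creatinine-corrected tertiles are scale invariant", {
  co <- quick_cohort(n = 60, seed = 3)
  comp <- substitute_lod_sqrt2(apply_correction_factors(co$mothers))
  cc <- creatinine_correct(comp$MEP, comp$creatinine)
  t1 <- tertile_categorize(cc)
  t2 <- tertile_categorize(7.3 * cc)
  expect_equal(t1$category, t2$category)
})
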