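test_that("default registry defines nine metabolites with a DEHP quartet", {
  reg <- default_registry()
  expect_equal(nrow(reg), 9)
  expect_equal(sum(reg$group == "DEHP"), 4)
  expect_setequal(reg$code[reg$group == "DEHP"],
                  c("MECPP", "MEHHP", "MEHP", "MEOHP"))
  expect_true(all(reg$lod > 0))
  expect_true(all(reg$correction_factor > 0 & reg$correction_factor <= 1))
})

test_that("registry validation rejects bad rows and round-trips cleanly", {
  reg <- default_registry()
  bad <- reg; bad$lod[3] <- 0
  expect_error(validate_registry(bad), "lod")
  dup <- rbind(reg, reg[1, ])
  expect_error(validate_registry(dup), "duplicate")

  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(reg, path)
  expect_equal(read_registry(path), reg)

  # schema error on a missing column
  trunc <- reg[, -2]
  utils::write.csv(trunc, path, row.names = FALSE)
  expect_error(read_registry(path), "missing column")
})

test_that("mothers records survive a write/read round trip incl. <LOD cells", {
  co <- quick_cohort(n = 40, seed = 2)
  m <- co$mothers
  expect_gt(sum(m$cens_MEHP), 0)   # some censored cells exercised
  path <- withr::local_tempfile(fileext = ".csv")
  write_mothers(m, path)
  expect_true(any(grepl("<LOD", readLines(path), fixed = TRUE)))
  m2 <- read_mothers(path)
  for (code in default_registry()$code) {
    expect_identical(m2[[code]], m[[code]])
    expect_identical(m2[[paste0("cens_", code)]],
                     m[[paste0("cens_", code)]])
  }
  expect_identical(m2$creatinine, m$creatinine)
  expect_identical(m2$collection_date, m$collection_date)
  expect_identical(m2$breastfed, m$breastfed)
  expect_identical(m2$last_preg_weight, m$last_preg_weight)
})

test_that("read_mothers validates schema and values", {
  m <- tiny_mothers()
  path <- withr::local_tempfile(fileext = ".csv")
  write_mothers(m, path)
  ok <- read_mothers(path)
  expect_equal(nrow(ok), 2)

  # a censored cell sets the flag and stores the LOD placeholder
  lines <- readLines(path)
  lines[2] <- sub("^A1,10", "A1,<LOD", lines[2])  # MEP cell
  writeLines(lines, path)
  m2 <- read_mothers(path)
  expect_true(m2$cens_MEP[1])
  expect_equal(m2$MEP[1], default_registry()$lod[1])

  # unknown metabolite column
  bad <- read.csv(path, check.names = FALSE)
  bad$XYZ <- 1
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_mothers(path), "unknown metabolite")

  # negative creatinine
  m3 <- tiny_mothers(); m3$creatinine[1] <- -5
  write_mothers(m3, path)
  expect_error(read_mothers(path), "creatinine")

  # required covariate missing -> record rejected with warning
  m4 <- tiny_mothers(); m4$prepreg_bmi[2] <- NA
  write_mothers(m4, path)
  expect_warning(kept <- read_mothers(path), "rejected")
  expect_equal(nrow(kept), 1)
})

test_that("read_visits enforces consistency and flags orphans", {
  v <- tiny_visits()
  path <- withr::local_tempfile(fileext = ".csv")
  write_visits(v, path)
  v2 <- read_visits(path)
  expect_equal(nrow(v2), 4)
  expect_equal(sum(v2$outcome_missing == 0), 3)
  expect_identical(v2$fat_mass, v$fat_mass)

  dup <- rbind(v, v[1, ])
  write_visits(dup, path)
  expect_error(read_visits(path), "duplicate")

  bad <- v; bad$fat_mass[1] <- bad$weight[1]
  write_visits(bad, path)
  expect_error(read_visits(path), "fat_mass")

  incons <- v; incons$outcome_missing[1] <- 1
  write_visits(incons, path)
  expect_error(read_visits(path), "consistency")

  write_visits(v[0, ], path)
  expect_warning(empty <- read_visits(path), "empty")
  expect_equal(nrow(empty), 0)

  write_visits(v, path)
  m <- tiny_mothers()[1, ]
  expect_warning(flagged <- read_visits(path, mothers = m), "orphan")
  expect_equal(sum(flagged$orphan), 2)
})

test_that("LMS reference tables are validated", {
  lms <- data.frame(sex = c(0, 0, 1, 1), age_months = c(48, 120, 48, 120),
                    L = c(-2, -2.2, -1.8, -2), M = c(15.8, 16.4, 16, 16.6),
                    S = c(0.08, 0.12, 0.08, 0.11))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(lms, path, row.names = FALSE)
  expect_equal(read_lms(path)$M, lms$M)
  lms$M[1] <- -1
  write.csv(lms, path, row.names = FALSE)
  expect_error(read_lms(path), "M and S")
})
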