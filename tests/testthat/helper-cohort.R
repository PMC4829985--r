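# Shared fixture builders.  Everything is generated in code; no data files.

quick_cohort <- function(n = 60, seed = 1, ...) {
  simulate_cohort(truth_config(n_children = as.integer(n), ...), seed = seed)
}

quick_spec <- function(burn = 200, iters = 600, chains = 1, seed = 1, ...) {
  model_spec(mcmc = list(burn_in = burn, iterations = iters,
                         chains = chains, seed = seed), ...)
}

# hand-built two-mother records in the read_mothers() internal format
tiny_mothers <- function(registry = default_registry()) {
  df <- data.frame(subject_id = c("A1", "A2"), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(registry))) {
    code <- registry$code[k]
    df[[code]] <- c(10, 2.5)
    df[[paste0("cens_", code)]] <- c(FALSE, FALSE)
  }
  df$creatinine <- c(120, 80)
  df$collection_date <- as.Date(c("1999-03-01", "2000-07-15"))
  df$race_ethnicity <- c("white", "hispanic")
  df$maternal_age <- c(24, 31)
  df$education <- c(1, 0)
  df$work_status <- c(1, 1)
  df$smoking <- c(0, 1)
  df$prepreg_bmi <- c(22, 27)
  df$maternal_height <- c(1.6, 1.7)
  df$first_preg_weight <- c(57, 79)
  df$last_preg_weight <- c(70, NA)
  df$gestational_age <- c(39, 40)
  df$birth_weight <- c(3200, 3600)
  df$child_sex <- c(1, 0)
  df$breastfed <- c(1, NA)
  df
}

tiny_visits <- function() {
  data.frame(subject_id = rep(c("A1", "A2"), each = 2),
             visit = rep(1:2, 2),
             age_months = c(59, 73, 60, 74),
             weight = c(20, 24, 19, 23),
             fat_mass = c(4, 5, NA, 4.6),
             height = c(1.10, 1.18, 1.08, 1.16),
             active = c(1, 0, 1, 1),
             outcome_missing = c(0, 0, 1, 0),
             stringsAsFactors = FALSE)
}

# rejection-sampling oracle for the upper-truncated normal
rtnorm_reject <- function(n, mean, sd, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mean, sd)
    out <- c(out, x[x <= upper])
  }
  out[seq_len(n)]
}
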