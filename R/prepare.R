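# Assembles everything the Gibbs sampler needs: the analysis sample, frozen
# standardization constants, censoring information, the fixed-effects design
# matrix with its prior precisions, and the three covariate-imputation
# submodel designs.

cov_mu_sd <- function(x, what) {
  x <- x[!is.na(x)]
  m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s <= 0)
    stop("degenerate covariate (zero SD): ", what)
  c(mu = m, sd = s)
}

#' Prepare data for the joint Bayesian model
#'
#' Runs the deterministic preprocessing chain (correction factors, dilute
#' exclusion, analysis-sample selection, frozen standardization constants,
#' censoring bookkeeping, tertiles when requested) and builds the design.
#'
#' Under MAR the analysis sample is children with at least one observed
#' outcome and only their observed visit rows enter the model; under MNAR
#' all mothers with measured exposures enter, every potential visit row is
#' modeled, and children with no visit rows at all contribute rows at the
#' visit-schedule mean ages.
#'
#' @param mothers,visits Data as read by \code{\link{read_mothers}} /
#'   \code{\link{read_visits}} (or simulated).
#' @param spec A \code{\link{model_spec}}.
#' @param registry Metabolite registry.
#' @param selection A \code{\link{selection_spec}} (required when
#'   \code{spec$missingness == "MNAR"}).
#' @return A model context (list) consumed by \code{\link{gibbs_sweep}} and
#'   \code{\link{phthalmix_fit}}; notable elements: \code{X} (initial design
#'   matrix), \code{col_info} (column metadata incl. prior precisions),
#'   \code{constants} (frozen exposure constants).
#' @export
prepare_model_data <- function(mothers, visits, spec = model_spec(),
                               registry = default_registry(),
                               selection = NULL) {
  corrected <- apply_correction_factors(mothers, registry)
  corrected <- exclude_dilute(corrected)$kept
  visits <- visits[visits$subject_id %in% corrected$subject_id, , drop = FALSE]

  mnar <- spec$missingness == "MNAR"
  if (mnar && is.null(selection)) selection <- selection_spec()

  y_all <- percent_fat_mass(visits$fat_mass, visits$weight)
  obs_ids <- unique(visits$subject_id[!is.na(y_all)])
  if (!length(obs_ids)) stop("no observed outcomes in the data")

  if (mnar) {
    visits <- complete_visit_rows(visits, corrected$subject_id)
    keep_ids <- corrected$subject_id
  } else {
    visits <- visits[!is.na(y_all), , drop = FALSE]
    keep_ids <- obs_ids
  }
  moth <- corrected[corrected$subject_id %in% keep_ids, , drop = FALSE]
  for (a in c("lods", "registry")) attr(moth, a) <- attr(corrected, a)
  # canonical ordering: results are invariant to input row permutations
  moth <- moth[order(moth$subject_id), , drop = FALSE]
  rownames(moth) <- NULL
  for (a in c("lods", "registry")) attr(moth, a) <- attr(corrected, a)
  visits <- visits[order(visits$subject_id, visits$visit), , drop = FALSE]
  rownames(visits) <- NULL

  n_child <- nrow(moth)
  N <- nrow(visits)
  row_child <- match(visits$subject_id, moth$subject_id)
  if (any(is.na(row_child)))
    stop("visit rows reference subjects without mother records")
  y <- percent_fat_mass(visits$fat_mass, visits$weight)
  obs <- !is.na(y)

  # frozen exposure constants from the LOD/sqrt(2)-completed analysis sample
  completed <- substitute_lod_sqrt2(moth)
  constants <- exposure_constants(completed)
  lods <- attr(moth, "lods")

  # censoring bookkeeping: frozen truncated-normal imputation parameters
  # from the observed (above-LOD) natural-log distribution
  cens_info <- list()
  for (code in registry$code) {
    cens <- moth[[paste0("cens_", code)]]
    if (!any(cens)) next
    ln_obs <- log(moth[[code]][!cens])
    if (length(ln_obs) < 2)
      stop("cannot freeze imputation moments for ", code,
           ": fewer than 2 observed values")
    s <- stats::sd(ln_obs)
    if (s <= 0) stop("degenerate observed distribution for ", code)
    cens_info[[code]] <- list(idx = which(cens), mu = mean(ln_obs), sd = s,
                              bound = log(lods[[code]]))
  }

  # current completed log-concentration matrix (corrected scale); censored
  # cells start at LOD/sqrt(2) and are re-imputed every sweep
  ln_conc <- log(as.matrix(completed[registry$code]))

  # covariate constants (frozen)
  ln_creat <- log(moth$creatinine)
  date_days <- as.numeric(moth$collection_date -
                            min(moth$collection_date))
  iom <- iom_defaults()
  prepreg_weight <- moth$prepreg_bmi * moth$maternal_height^2
  rate <- iom$rates_kg_wk[bmi_class(moth$prepreg_bmi)]
  expected_gain <- iom$base_gain_kg +
    as.numeric(rate) * pmax(0, moth$gestational_age - 13)
  gwg_ratio <- 100 * (moth$last_preg_weight - prepreg_weight) / expected_gain

  cc <- list(
    maternal_age = cov_mu_sd(moth$maternal_age, "maternal_age"),
    prepreg_bmi = cov_mu_sd(moth$prepreg_bmi, "prepreg_bmi"),
    maternal_height = cov_mu_sd(moth$maternal_height, "maternal_height"),
    gwg_ratio = cov_mu_sd(gwg_ratio, "gwg_ratio"),
    date_days = cov_mu_sd(date_days, "collection_date"),
    ln_creatinine = cov_mu_sd(ln_creat, "ln_creatinine"),
    age_months = cov_mu_sd(visits$age_months, "age_months"),
    birth_weight = cov_mu_sd(moth$birth_weight, "birth_weight"),
    first_preg_weight = cov_mu_sd(moth$first_preg_weight,
                                  "first_preg_weight"),
    gestational_age = cov_mu_sd(moth$gestational_age, "gestational_age"),
    last_preg_weight = cov_mu_sd(moth$last_preg_weight, "last_preg_weight"))

  # tertile assignment (frozen; creatinine-corrected, analysis sample)
  tertiles <- NULL
  if (spec$exposure_coding == "tertile") {
    tertiles <- list()
    for (e in spec$exposures) {
      conc <- if (e == "SumDEHP") molar_sum_dehp(completed, registry)
              else completed[[e]]
      tertiles[[e]] <- tertile_categorize(
        creatinine_correct(conc, moth$creatinine))
    }
  }

  ctx <- list(
    spec = spec, selection = selection, registry = registry,
    mothers = moth, visits = visits, n_child = n_child, N = N,
    row_child = row_child, y = y, obs = obs, mis_idx = which(!obs),
    constants = constants, lods = lods, cens_info = cens_info,
    ln_conc0 = ln_conc, cov_const = cc, tertiles = tertiles,
    prepreg_weight = prepreg_weight, expected_gain = expected_gain,
    gwg_ratio0 = gwg_ratio,
    ln_creat_std = std2(ln_creat, cc$ln_creatinine["mu"],
                        cc$ln_creatinine["sd"]),
    date_std = std2(date_days, cc$date_days["mu"], cc$date_days["sd"]),
    age_std = std2(visits$age_months, cc$age_months["mu"],
                   cc$age_months["sd"]),
    sex = moth$child_sex,
    W_missing = which(is.na(moth$last_preg_weight)),
    B_missing = which(is.na(moth$breastfed)),
    A_missing = which(is.na(visits$active)))
  ctx$rows_of_child <- split(seq_len(N), row_child)
  ctx$expo_mu <- stats::setNames(constants$exposure$mean,
                                 constants$exposure$code)
  ctx$expo_sd <- stats::setNames(constants$exposure$sd,
                                 constants$exposure$code)
  ctx$dehp_cols <- dehp_codes(registry)
  ctx$dehp_inv_mw <- 1 / registry$mol_weight[match(ctx$dehp_cols,
                                                   registry$code)]

  ctx <- build_design(ctx)
  ctx <- build_submodel_designs(ctx)
  ctx$ZtZ_W <- crossprod(ctx$Z_W)
  if (mnar) ctx <- build_selection_design(ctx)
  ctx
}

# For the selection analysis every child contributes a row for each
# potential visit; children entirely absent from follow-up get rows at the
# visit-schedule mean ages.
complete_visit_rows <- function(visits, subject_ids) {
  nvis <- max(visits$visit, 3)
  sched <- vapply(seq_len(nvis), function(v) {
    a <- visits$age_months[visits$visit == v]
    if (length(a)) mean(a) else NA_real_
  }, numeric(1))
  add <- list()
  for (sid in setdiff(subject_ids, unique(visits$subject_id))) {
    add[[sid]] <- data.frame(subject_id = sid, visit = seq_len(nvis),
                             age_months = sched, weight = NA_real_,
                             fat_mass = NA_real_, height = NA_real_,
                             active = NA_real_, outcome_missing = 1,
                             stringsAsFactors = FALSE)
  }
  if (length(add)) {
    common <- c("subject_id", "visit", "age_months", "weight", "fat_mass",
                "height", "active", "outcome_missing")
    visits <- rbind(visits[common], do.call(rbind, c(add, make.row.names = FALSE)))
  }
  visits
}

# mother-level exposure score matrix given current log concentrations
# (hot path: uses the flat constant vectors precomputed in the context)
exposure_scores <- function(ctx, ln_conc) {
  spec <- ctx$spec
  mu <- ctx$expo_mu %||%
    stats::setNames(ctx$constants$exposure$mean, ctx$constants$exposure$code)
  sdv <- ctx$expo_sd %||%
    stats::setNames(ctx$constants$exposure$sd, ctx$constants$exposure$code)
  out <- matrix(NA_real_, nrow(ln_conc), length(spec$exposures),
                dimnames = list(NULL, spec$exposures))
  for (e in spec$exposures) {
    lnv <- if (e == "SumDEHP")
      log(as.numeric(exp(ln_conc[, ctx$dehp_cols, drop = FALSE]) %*%
                       ctx$dehp_inv_mw))
    else ln_conc[, e]
    out[, e] <- (lnv - mu[[e]]) / sdv[[e]]
  }
  out
}

#' Build the fixed-effects design
#'
#' Constructs the design matrix for the outcome model in the fixed column
#' order: intercept; exposures (standardized ln concentrations, or second-
#' and third-tertile indicators); child sex; standardized age; sex x age;
#' race/ethnicity indicators; education; work status; smoking;
#' breastfeeding; physical activity; standardized maternal height; raw
#' polynomial expansions of standardized maternal age (cubic),
#' prepregnancy BMI (quadratic) and gestational weight-gain adequacy
#' (cubic); ln creatinine (quadratic; continuous coding only); standardized
#' collection date; and, in interaction mode, sex x exposure products plus
#' sex x ln creatinine (linear).  Each column carries its prior precision
#' (\code{tau_exposure} for exposure and sex x exposure columns,
#' \code{tau_covariate} otherwise).
#'
#' @param ctx Model context from \code{\link{prepare_model_data}} (called
#'   internally; exposed for inspection and tests).
#' @return The context with \code{X}, \code{col_info} and dynamic-column
#'   indices attached.
#' @keywords internal
#' @export
build_design <- function(ctx) {
  spec <- ctx$spec
  N <- ctx$N
  rc <- ctx$row_child
  sex_row <- ctx$sex[rc]
  cols <- list(); prec <- c(); grp <- c()
  addcol <- function(name, value, group) {
    cols[[name]] <<- value
    grp[name] <<- group
    prec[name] <<- if (group %in% c("exposure", "sex_exposure"))
      spec$tau_exposure else spec$tau_covariate
  }
  addcol("(Intercept)", rep(1, N), "covariate")

  expo_names <- c()
  if (spec$exposure_coding == "continuous") {
    E0 <- exposure_scores(ctx, ctx$ln_conc0)
    for (e in spec$exposures) {
      addcol(e, E0[rc, e], "exposure")
      expo_names <- c(expo_names, e)
    }
  } else {
    for (e in spec$exposures) {
      addcol(paste0(e, "_T2"), ctx$tertiles[[e]]$t2[rc], "exposure")
      addcol(paste0(e, "_T3"), ctx$tertiles[[e]]$t3[rc], "exposure")
      expo_names <- c(expo_names, paste0(e, c("_T2", "_T3")))
    }
  }

  addcol("sex", sex_row, "covariate")
  addcol("age_std", ctx$age_std, "covariate")
  addcol("sex:age_std", sex_row * ctx$age_std, "covariate")
  addcol("race_black", as.numeric(ctx$mothers$race_ethnicity == "black")[rc],
         "covariate")
  addcol("race_hispanic",
         as.numeric(ctx$mothers$race_ethnicity == "hispanic")[rc],
         "covariate")
  for (v in c("education", "work_status", "smoking"))
    addcol(v, ctx$mothers[[v]][rc], "covariate")

  bf0 <- ctx$mothers$breastfed
  bf0[is.na(bf0)] <- round(mean(bf0, na.rm = TRUE))
  addcol("breastfed", bf0[rc], "covariate")
  act0 <- ctx$visits$active
  act0[is.na(act0)] <- round(mean(act0, na.rm = TRUE))
  addcol("active", act0, "covariate")

  cc <- ctx$cov_const
  addcol("height_std", std2(ctx$mothers$maternal_height[rc],
                            cc$maternal_height["mu"],
                            cc$maternal_height["sd"]), "covariate")
  poly_add <- function(base, x, deg) {
    for (d in seq_len(deg))
      addcol(if (d == 1) base else paste0(base, d), x^d, "covariate")
  }
  poly_add("mat_age_std",
           std2(ctx$mothers$maternal_age[rc], cc$maternal_age["mu"],
                cc$maternal_age["sd"]), spec$poly_degrees[["maternal_age"]])
  poly_add("ppbmi_std",
           std2(ctx$mothers$prepreg_bmi[rc], cc$prepreg_bmi["mu"],
                cc$prepreg_bmi["sd"]), spec$poly_degrees[["prepreg_bmi"]])
  gwg0 <- ctx$gwg_ratio0
  gwg0[is.na(gwg0)] <- cc$gwg_ratio["mu"]
  poly_add("gwg_std", std2(gwg0, cc$gwg_ratio["mu"], cc$gwg_ratio["sd"])[rc],
           spec$poly_degrees[["gwg_adequacy"]])
  if (spec$include_creatinine)
    poly_add("lncreat_std", ctx$ln_creat_std[rc],
             spec$poly_degrees[["ln_creatinine"]])
  addcol("date_std", ctx$date_std[rc], "covariate")

  het_names <- c()
  if (spec$interaction == "sex") {
    for (e in expo_names) {
      nm <- paste0("sex:", e)
      addcol(nm, sex_row * cols[[e]], "sex_exposure")
      het_names <- c(het_names, nm)
    }
    if (spec$include_creatinine)
      addcol("sex:lncreat_std", sex_row * ctx$ln_creat_std[rc], "covariate")
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  ctx$X <- X
  ctx$col_info <- list(names = colnames(X), prior_prec = prec, group = grp,
                       exposure = expo_names, heterogeneity = het_names,
                       gwg = grep("^gwg_std", colnames(X), value = TRUE))
  ctx$sex_row <- sex_row
  ctx
}

# designs for the three covariate-imputation submodels ----------------------
build_submodel_designs <- function(ctx) {
  m <- ctx$mothers
  cc <- ctx$cov_const
  race_black <- as.numeric(m$race_ethnicity == "black")
  race_hisp <- as.numeric(m$race_ethnicity == "hispanic")
  s2 <- function(x, k) std2(x, cc[[k]]["mu"], cc[[k]]["sd"])

  ctx$Z_W <- cbind("(Intercept)" = 1, education = m$education,
                   race_black = race_black, race_hispanic = race_hisp,
                   child_sex = m$child_sex, smoking = m$smoking,
                   work_status = m$work_status,
                   mat_age_std = s2(m$maternal_age, "maternal_age"),
                   birthw_std = s2(m$birth_weight, "birth_weight"),
                   height_std = s2(m$maternal_height, "maternal_height"),
                   gestage_std = s2(m$gestational_age, "gestational_age"),
                   firstw_std = s2(m$first_preg_weight, "first_preg_weight"),
                   ppbmi_std = s2(m$prepreg_bmi, "prepreg_bmi"))

  gwg_std0 <- std2(ctx$gwg_ratio0, cc$gwg_ratio["mu"], cc$gwg_ratio["sd"])
  gwg_std0[is.na(gwg_std0)] <- 0
  ctx$Z_B <- cbind("(Intercept)" = 1, education = m$education,
                   race_black = race_black, race_hispanic = race_hisp,
                   child_sex = m$child_sex, smoking = m$smoking,
                   work_status = m$work_status,
                   mat_age_std = s2(m$maternal_age, "maternal_age"),
                   gwg_std = gwg_std0,
                   ppbmi_std = s2(m$prepreg_bmi, "prepreg_bmi"),
                   birthw_std = s2(m$birth_weight, "birth_weight"))
  ctx$Z_B_gwg_col <- which(colnames(ctx$Z_B) == "gwg_std")

  rc <- ctx$row_child
  ctx$Z_A <- cbind("(Intercept)" = 1, race_black = race_black[rc],
                   race_hispanic = race_hisp[rc],
                   ppbmi_std = s2(m$prepreg_bmi, "prepreg_bmi")[rc],
                   smoking = m$smoking[rc], age_std = ctx$age_std,
                   birthw_std = s2(m$birth_weight, "birth_weight")[rc],
                   child_sex = m$child_sex[rc])
  ctx
}

build_selection_design <- function(ctx) {
  sel <- ctx$selection
  m <- ctx$mothers
  rc <- ctx$row_child
  cc <- ctx$cov_const
  s2 <- function(x, k) std2(x, cc[[k]]["mu"], cc[[k]]["sd"])
  cols <- list("(Intercept)" = rep(1, ctx$N))
  for (v in sel$covariates) {
    cols[[v]] <- switch(v,
      maternal_age = s2(m$maternal_age, "maternal_age")[rc],
      race_ethnicity = NULL,  # handled below (two indicators)
      prepreg_bmi = s2(m$prepreg_bmi, "prepreg_bmi")[rc],
      gwg_adequacy = {
        g <- std2(ctx$gwg_ratio0, cc$gwg_ratio["mu"], cc$gwg_ratio["sd"])
        g[is.na(g)] <- 0   # refreshed each sweep for imputed mothers
        g[rc]
      },
      child_sex = m$child_sex[rc],
      age_months = ctx$age_std,
      smoking = m$smoking[rc],
      breastfed = {
        bf <- m$breastfed; bf[is.na(bf)] <- round(mean(bf, na.rm = TRUE))
        bf[rc]
      },
      education = m$education[rc],
      work_status = m$work_status[rc],
      birth_weight = s2(m$birth_weight, "birth_weight")[rc])
    if (v == "race_ethnicity") {
      cols[["race_black"]] <- as.numeric(m$race_ethnicity == "black")[rc]
      cols[["race_hispanic"]] <- as.numeric(m$race_ethnicity == "hispanic")[rc]
    }
  }
  cols <- Filter(Negate(is.null), cols)
  Zs <- do.call(cbind, cols)
  colnames(Zs) <- names(cols)
  ctx$Z_sel <- Zs
  ctx$Z_sel_gwg_col <- which(colnames(Zs) == "gwg_adequacy")
  ctx$Z_sel_bf_col <- which(colnames(Zs) == "breastfed")
  # the tau_selection shrinkage applies to the coefficients; the intercept
  # (the baseline missingness log-odds, far from zero) gets a vague prior
  prec <- rep(sel$tau_selection, ncol(Zs) + 1)
  names(prec) <- c(colnames(Zs), "y")
  prec["(Intercept)"] <- 0.01
  ctx$sel_prior_prec <- prec
  ctx
}
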