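# Analysis configuration objects.

#' Outcome-model specification
#'
#' Captures the full analysis configuration: which exposures enter the
#' mixed model and how they are coded, the interaction mode, the shrinkage
#' prior precisions, polynomial degrees for nonlinear covariates, variance
#' priors and MCMC settings.
#'
#' Priors are null-centred normals with variance \code{1/tau} (tau is a
#' precision): \code{tau_exposure = 1/16} places 95% of exposure effects
#' within about one SD of mean percent fat mass, \code{tau_covariate = 1/64}
#' within about two SDs, and \code{tau_imputation = 1} corresponds to an
#' odds ratio range of roughly 0.14-7.1 for the logistic imputation
#' submodels.
#'
#' @param exposure_coding \code{"continuous"} (standardized ln
#'   concentration) or \code{"tertile"} (indicators for the 2nd/3rd tertile
#'   of the creatinine-corrected concentration).
#' @param exposures Character vector of exposure codes; metabolite codes
#'   and/or \code{"SumDEHP"}.
#' @param interaction \code{"none"} or \code{"sex"} (adds sex x exposure
#'   products and, in continuous coding, sex x ln creatinine).
#' @param tau_exposure,tau_covariate,tau_imputation Prior precisions.
#' @param poly_degrees Named integer vector of polynomial degrees for
#'   maternal age, prepregnancy BMI, gestational weight-gain adequacy and
#'   ln creatinine.
#' @param variance_prior List: inverse-gamma shape \code{a} and rate
#'   \code{b} for the residual, random-intercept and submodel variances.
#' @param include_creatinine \code{NULL} (automatic: included for
#'   continuous coding, dropped for tertile coding) or logical; requesting
#'   creatinine terms together with tertile coding is a configuration
#'   error since tertiles are already creatinine-corrected.
#' @param missingness \code{"MAR"} (primary analysis, children with at
#'   least one observed outcome) or \code{"MNAR"} (joint selection model
#'   over the full cohort).
#' @param sigma_b_fixed Optionally fix the random-intercept SD (0 removes
#'   the random intercepts; used for conjugate-limit checks).
#' @param mcmc List: \code{burn_in}, \code{iterations} (post burn-in),
#'   \code{chains}, \code{thin}, \code{seed}.
#' @return Object of class \code{"model_spec"}.
#' @export
model_spec <- function(exposure_coding = c("continuous", "tertile"),
                       exposures = c("MEP", "MnBP", "MiBP", "MCPP", "MBzP",
                                     "SumDEHP"),
                       interaction = c("none", "sex"),
                       tau_exposure = 1 / 16,
                       tau_covariate = 1 / 64,
                       tau_imputation = 1,
                       poly_degrees = c(maternal_age = 3, prepreg_bmi = 2,
                                        gwg_adequacy = 3, ln_creatinine = 2),
                       variance_prior = list(a = 0.001, b = 0.001),
                       include_creatinine = NULL,
                       missingness = c("MAR", "MNAR"),
                       sigma_b_fixed = NULL,
                       mcmc = list()) {
  exposure_coding <- match.arg(exposure_coding)
  interaction <- match.arg(interaction)
  missingness <- match.arg(missingness)
  if (any(c(tau_exposure, tau_covariate, tau_imputation) <= 0))
    stop("model_spec: prior precisions must be > 0")
  if (any(poly_degrees < 1)) stop("model_spec: polynomial degrees must be >= 1")
  if (exposure_coding == "tertile" && isTRUE(include_creatinine))
    stop("model_spec config error: tertile coding uses creatinine-corrected ",
         "concentrations and must not include ln creatinine as a covariate")
  mcmc_def <- list(burn_in = 10000L, iterations = 50000L, chains = 2L,
                   thin = 1L, seed = 1L)
  mcmc_def[names(mcmc)] <- mcmc
  if (mcmc_def$burn_in < 0 || mcmc_def$iterations <= 0)
    stop("model_spec: need burn_in >= 0 and iterations > 0")
  structure(list(exposure_coding = exposure_coding, exposures = exposures,
                 interaction = interaction, tau_exposure = tau_exposure,
                 tau_covariate = tau_covariate,
                 tau_imputation = tau_imputation,
                 poly_degrees = poly_degrees,
                 variance_prior = variance_prior,
                 include_creatinine =
                   include_creatinine %||% (exposure_coding == "continuous"),
                 missingness = missingness,
                 sigma_b_fixed = sigma_b_fixed,
                 mcmc = mcmc_def),
            class = "model_spec")
}

#' Missingness (selection) model specification
#'
#' Configuration of the logistic model for the indicator that a percent
#' fat mass value is missing at a follow-up visit, fitted jointly with the
#' outcome model under a potentially nonignorable mechanism.  The
#' missingness probability may depend on the possibly unobserved outcome
#' itself (coefficient \code{gamma_y}, per 1% fat mass).
#'
#' @param covariates Covariates entering the missingness model; any of
#'   \code{"maternal_age"}, \code{"race_ethnicity"}, \code{"prepreg_bmi"},
#'   \code{"gwg_adequacy"}, \code{"child_sex"}, \code{"age_months"},
#'   \code{"smoking"}, \code{"breastfed"}, \code{"education"},
#'   \code{"work_status"}, \code{"birth_weight"}.
#' @param tau_selection Prior precision for the selection coefficients
#'   (default 2: 95% prior odds ratios within 0.25-4).
#' @param chains Number of chains for selection-model inference.
#' @param fix_gamma_y Optionally fix the outcome-dependence coefficient
#'   (0 recovers an ignorable fit; used for equivalence checks).
#' @return Object of class \code{"selection_spec"}.
#' @export
selection_spec <- function(covariates = c("maternal_age", "race_ethnicity",
                                          "prepreg_bmi", "gwg_adequacy",
                                          "child_sex", "age_months"),
                           tau_selection = 2, chains = 10L,
                           fix_gamma_y = NULL) {
  allowed <- c("maternal_age", "race_ethnicity", "prepreg_bmi",
               "gwg_adequacy", "child_sex", "age_months", "smoking",
               "breastfed", "education", "work_status", "birth_weight")
  bad <- setdiff(covariates, allowed)
  if (length(bad))
    stop("selection_spec: unknown covariate(s): ", paste(bad, collapse = ", "))
  if (tau_selection <= 0) stop("selection_spec: tau_selection must be > 0")
  if (chains < 1) stop("selection_spec: chains must be >= 1")
  structure(list(covariates = covariates, tau_selection = tau_selection,
                 chains = as.integer(chains), fix_gamma_y = fix_gamma_y),
            class = "selection_spec")
}
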