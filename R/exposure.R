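# Deterministic exposure preprocessing: analytical correction factors,
# dilute-urine exclusion, below-LOD substitution for descriptives,
# creatinine correction, DEHP molar sums, standardization, tertiles.

#' Apply analytical correction factors to concentrations and LODs
#'
#' Scales each metabolite's concentrations *and* its limit of detection by
#' the registry correction factor (MBzP 0.72, MEP 0.66, all others 1).
#' Censored cells hold the LOD placeholder and are scaled identically, so
#' correction commutes with any later LOD-based substitution.
#'
#' @param mothers Mother records (see \code{\link{read_mothers}}).
#' @param registry Metabolite registry.
#' @return The records with corrected concentrations, carrying the corrected
#'   LODs as attribute \code{"lods"} (named numeric vector) and the registry
#'   as attribute \code{"registry"}.
#' @export
apply_correction_factors <- function(mothers, registry = default_registry()) {
  out <- mothers
  lods <- stats::setNames(registry$lod * registry$correction_factor,
                          registry$code)
  for (k in seq_len(nrow(registry))) {
    code <- registry$code[k]
    if (any(!out[[paste0("cens_", code)]] & out[[code]] <= 0))
      stop("exposure value error: non-positive observed ", code)
    out[[code]] <- out[[code]] * registry$correction_factor[k]
  }
  attr(out, "lods") <- lods
  attr(out, "registry") <- registry
  out
}

#' Exclude very dilute urine samples
#'
#' Removes records whose urinary creatinine is strictly below the threshold
#' (default 10 mg/dL), where biomarker measurements are considered
#' unreliable.
#'
#' @param records Mother records.
#' @param threshold_mg_dl Exclusion threshold, mg/dL (strict \code{<}).
#' @return \code{list(kept = ..., excluded = ...)}.
#' @export
exclude_dilute <- function(records, threshold_mg_dl = 10) {
  if (any(is.na(records$creatinine)))
    stop("exposure value error: creatinine missing")
  dilute <- records$creatinine < threshold_mg_dl
  kept <- records[!dilute, , drop = FALSE]
  rownames(kept) <- NULL
  excluded <- records[dilute, , drop = FALSE]
  rownames(excluded) <- NULL
  for (a in c("lods", "registry")) {
    attr(kept, a) <- attr(records, a)
    attr(excluded, a) <- attr(records, a)
  }
  list(kept = kept, excluded = excluded)
}

#' Substitute LOD/sqrt(2) for censored cells (descriptive analyses)
#'
#' Replaces each below-LOD concentration by its corrected LOD divided by the
#' square root of two.  Used only for descriptive statistics and for the
#' frozen standardization constants; modelling imputes censored cells from a
#' truncated normal inside the MCMC instead.
#'
#' @param matrix_corrected Output of \code{\link{apply_correction_factors}}.
#' @return The records with censored cells substituted (censor flags kept).
#' @export
substitute_lod_sqrt2 <- function(matrix_corrected) {
  lods <- attr(matrix_corrected, "lods")
  if (is.null(lods))
    stop("substitute_lod_sqrt2 expects a correction-factor-applied matrix")
  out <- matrix_corrected
  for (code in names(lods)) {
    cens <- out[[paste0("cens_", code)]]
    out[[code]][cens] <- lods[[code]] / sqrt(2)
  }
  out
}

#' Molar sum of the four DEHP metabolites
#'
#' \eqn{\sum_k c_k / MW_k} over MECPP, MEHHP, MEHP, MEOHP with
#' concentrations in ug/L and molecular weights in ug/umol, giving umol/L.
#'
#' @param values Named numeric vector, matrix or data.frame holding the four
#'   DEHP component concentrations (ug/L), named by metabolite code.
#' @param registry Metabolite registry.
#' @return Numeric vector of molar sums, umol/L.
#' @export
molar_sum_dehp <- function(values, registry = default_registry()) {
  codes <- dehp_codes(registry)
  if (length(codes) != 4)
    stop("registry must define exactly four DEHP metabolites")
  mw <- stats::setNames(registry$mol_weight, registry$code)[codes]
  if (is.vector(values) && !is.list(values)) {
    if (!all(codes %in% names(values)))
      stop("molar_sum_dehp: missing component(s): ",
           paste(setdiff(codes, names(values)), collapse = ", "))
    return(sum(values[codes] / mw))
  }
  if (!all(codes %in% colnames(values)))
    stop("molar_sum_dehp: missing component(s): ",
         paste(setdiff(codes, colnames(values)), collapse = ", "))
  as.numeric(as.matrix(values[, codes, drop = FALSE]) %*% (1 / mw))
}

#' Creatinine-correct a urinary concentration
#'
#' Divides by creatinine expressed in g/L (mg/dL x 0.01), yielding ug per g
#' creatinine for metabolites, or umol/g for the DEHP molar sum.
#'
#' @param conc Concentration, ug/L (or umol/L).
#' @param creatinine Urinary creatinine, mg/dL; must be > 0.
#' @return Corrected concentration, ug/g (or umol/g).
#' @export
creatinine_correct <- function(conc, creatinine) {
  if (any(!is.finite(creatinine)) || any(creatinine <= 0))
    stop("creatinine_correct: creatinine must be > 0")
  conc / (creatinine * 0.01)
}

#' Descriptive statistics per metabolite
#'
#' Reproduces the format of a standard exposure-distribution table: percent
#' detected, geometric mean, minimum, 25th/75th percentile and maximum, with
#' below-LOD values replaced by LOD/sqrt(2) (already done if the input came
#' through \code{\link{substitute_lod_sqrt2}}).  Percentiles use linear
#' interpolation between order statistics (quantile type 7).  A DEHP molar
#' sum row (umol/L) is appended.
#'
#' @param completed Output of \code{\link{substitute_lod_sqrt2}}.
#' @return \code{data.frame} with one row per metabolite plus
#'   \code{"SumDEHP"}.
#' @export
descriptive_table <- function(completed) {
  registry <- attr(completed, "registry")
  if (is.null(registry))
    stop("descriptive_table expects a prepared exposure matrix")
  one <- function(x, detected) {
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    data.frame(percent_detected = detected,
               geometric_mean = exp(mean(log(x))),
               minimum = min(x), p25 = q[1], p75 = q[2], maximum = max(x))
  }
  rows <- lapply(registry$code, function(code) {
    det <- 100 * mean(!completed[[paste0("cens_", code)]])
    cbind(metabolite = code, one(completed[[code]], det))
  })
  sdehp <- molar_sum_dehp(completed, registry)
  any_cens <- Reduce(`|`, lapply(dehp_codes(registry),
                                 function(code) completed[[paste0("cens_", code)]]))
  rows <- c(rows, list(cbind(metabolite = "SumDEHP",
                             one(sdehp, 100 * mean(!any_cens)))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Frozen standardization constants for exposures and covariates
#'
#' Exposure constants are the mean and SD of the natural log of each
#' metabolite (and of the DEHP molar sum) over the LOD/sqrt(2)-completed
#' analysis sample; covariate constants are plain means and SDs.  Both are
#' computed once, before MCMC, and frozen.
#'
#' @param completed LOD/sqrt(2)-completed exposure matrix (analysis sample).
#' @return List with elements \code{exposure} (data.frame: code, mean, sd of
#'   ln concentration) and \code{lods} (corrected LODs).
#' @export
exposure_constants <- function(completed) {
  registry <- attr(completed, "registry")
  codes <- c(registry$code, "SumDEHP")
  lnval <- cbind(log(as.matrix(completed[registry$code])),
                 SumDEHP = log(molar_sum_dehp(completed, registry)))
  mu <- colMeans(lnval)
  sdv <- apply(lnval, 2, stats::sd)
  if (any(sdv <= 0)) stop("exposure_constants: degenerate (zero SD) exposure")
  list(exposure = data.frame(code = codes, mean = as.numeric(mu),
                             sd = as.numeric(sdv), stringsAsFactors = FALSE),
       lods = attr(completed, "lods"))
}

#' Standardize a log exposure to its frozen mean and SD
#'
#' @param ln_value Natural-log concentration(s).
#' @param constants Output of \code{\link{exposure_constants}}.
#' @param code Exposure code (a metabolite or \code{"SumDEHP"}).
#' @return Standardized value(s): \eqn{(\ln x - \mu)/\sigma}.
#' @export
standardize_exposure <- function(ln_value, constants, code) {
  row <- constants$exposure[constants$exposure$code == code, ]
  if (nrow(row) != 1) stop("unknown exposure code: ", code)
  std1(ln_value, row$mean, row$sd)
}

#' Standardize a continuous covariate by two standard deviations
#'
#' Continuous covariates are centred and scaled as \eqn{(x - \mu)/(2\sigma)}
#' so a one-unit change is a 2-SD change, comparable with a binary contrast.
#'
#' @param value Raw covariate value(s).
#' @param mu,sigma Frozen mean and SD.
#' @return Standardized value(s).
#' @export
standardize_covariate <- function(value, mu, sigma) {
  if (sigma <= 0) stop("standardize_covariate: sigma must be > 0")
  std2(value, mu, sigma)
}

#' Tertile categorization with indicator variables
#'
#' Cut points are the 1/3 and 2/3 empirical quantiles (type 7) of the
#' supplied analysis-sample values; a value exactly at a cut point goes to
#' the lower tertile.
#'
#' @param values Creatinine-corrected concentrations of the analysis sample.
#' @return List: \code{category} (integer 1-3 per value), \code{cutpoints}
#'   (length 2), \code{t2}, \code{t3} (0/1 indicators).
#' @export
tertile_categorize <- function(values) {
  if (any(!is.finite(values))) stop("tertile_categorize: non-finite values")
  q <- stats::quantile(values, c(1, 2) / 3, type = 7, names = FALSE)
  if (diff(range(values)) == 0 || q[1] == q[2])
    stop("tertile_categorize: degenerate tertiles (constant or heavily tied)")
  category <- 1L + (values > q[1]) + (values > q[2])
  list(category = as.integer(category), cutpoints = q,
       t2 = as.numeric(category == 2L), t3 = as.numeric(category == 3L))
}
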