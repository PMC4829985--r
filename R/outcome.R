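# Outcome and derived-covariate construction: percent fat mass, BMI and LMS
# z-scores, gestational weight-gain adequacy, physical-activity coding.

#' Percent fat mass
#'
#' @param fat_kg Fat mass, kg (may be NA).
#' @param weight_kg Body weight, kg.
#' @return \code{fat/weight * 100}, percent.
#' @export
percent_fat_mass <- function(fat_kg, weight_kg) {
  obs <- !is.na(fat_kg)
  if (any(obs & (fat_kg < 0 | fat_kg >= weight_kg)))
    stop("percent_fat_mass: need 0 <= fat < weight")
  100 * fat_kg / weight_kg
}

#' Body mass index
#'
#' @param weight_kg Weight, kg.
#' @param height_m Height, m; must be > 0.
#' @return BMI, kg/m^2.
#' @export
bmi <- function(weight_kg, height_m) {
  if (any(height_m <= 0, na.rm = TRUE)) stop("bmi: height must be > 0")
  weight_kg / height_m^2
}

#' LMS z-score
#'
#' Standard growth-reference transformation with skewness \code{L}, median
#' \code{M} and coefficient of variation \code{S}:
#' \eqn{z = ((x/M)^L - 1)/(L S)} for \eqn{L \neq 0}, with the analytic limit
#' \eqn{z = \ln(x/M)/S} at \eqn{L = 0}.
#'
#' @param x Measured value (e.g. BMI).
#' @param L,M,S LMS parameters; \code{M > 0}, \code{S > 0}.
#' @return z-score.
#' @export
lms_zscore <- function(x, L, M, S) {
  if (any(M <= 0) || any(S <= 0)) stop("lms_zscore: need M > 0, S > 0")
  n <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  z <- ifelse(L == 0, log(x / M) / S, ((x / M)^L - 1) / (L * S))
  as.numeric(z)
}

#' Age- and sex-standardized BMI z-score from an LMS reference table
#'
#' L, M and S are linearly interpolated in age within sex.
#'
#' @param bmi_value BMI, kg/m^2.
#' @param sex Binary sex code matching the reference table.
#' @param age_months Age in months.
#' @param lms LMS reference table (see \code{\link{read_lms}}).
#' @return z-scores; NA where age is outside the reference range.
#' @export
bmi_zscore <- function(bmi_value, sex, age_months, lms) {
  n <- length(bmi_value)
  z <- rep(NA_real_, n)
  for (s in unique(sex)) {
    ref <- lms[lms$sex == s, ]
    ref <- ref[order(ref$age_months), ]
    idx <- which(sex == s)
    if (nrow(ref) < 2) next
    inside <- age_months[idx] >= min(ref$age_months) &
      age_months[idx] <= max(ref$age_months)
    ii <- idx[inside]
    if (!length(ii)) next
    L <- stats::approx(ref$age_months, ref$L, age_months[ii])$y
    M <- stats::approx(ref$age_months, ref$M, age_months[ii])$y
    S <- stats::approx(ref$age_months, ref$S, age_months[ii])$y
    z[ii] <- lms_zscore(bmi_value[ii], L, M, S)
  }
  z
}

#' Default IOM-2009-style expected gestational weight gain parameters
#'
#' Expected gain = first-trimester base gain + weekly rate x weeks beyond 13,
#' with the weekly rate depending on prepregnancy BMI class.  Midpoint
#' defaults; fully configurable.
#'
#' @return List with \code{base_gain_kg}, \code{rates_kg_wk} (named by BMI
#'   class), and \code{bmi_breaks}.
#' @export
iom_defaults <- function() {
  list(base_gain_kg = 2.0,
       rates_kg_wk = c(under = 0.51, normal = 0.42, over = 0.28,
                       obese = 0.22),
       bmi_breaks = c(18.5, 25, 30))
}

bmi_class <- function(prepreg_bmi, breaks = iom_defaults()$bmi_breaks) {
  cls <- cut(prepreg_bmi, c(-Inf, breaks, Inf),
             labels = c("under", "normal", "over", "obese"), right = FALSE)
  as.character(cls)
}

#' Adequacy of gestational weight gain
#'
#' Ratio (percent) of observed gain (last pregnancy weight minus
#' prepregnancy weight) to expected gain under IOM-style recommendations,
#' categorized as less than recommended (< 86), recommended (86-120, both
#' endpoints inclusive) or more than recommended (> 120).
#'
#' @param last_weight,prepreg_weight Weights, kg (last may be NA).
#' @param gestational_age_wk Gestational age at delivery, weeks.
#' @param prepreg_bmi Prepregnancy BMI, kg/m^2 (selects the weekly rate).
#' @param iom_params See \code{\link{iom_defaults}}.
#' @return List: \code{ratio} (percent) and \code{category} (character).
#' @export
gwg_adequacy <- function(last_weight, prepreg_weight, gestational_age_wk,
                         prepreg_bmi, iom_params = iom_defaults()) {
  if (any(prepreg_weight <= 0, na.rm = TRUE) ||
      any(last_weight <= 0, na.rm = TRUE))
    stop("gwg_adequacy: weights must be > 0")
  rate <- iom_params$rates_kg_wk[bmi_class(prepreg_bmi,
                                           iom_params$bmi_breaks)]
  expected <- iom_params$base_gain_kg +
    as.numeric(rate) * pmax(0, gestational_age_wk - 13)
  ratio <- 100 * (last_weight - prepreg_weight) / expected
  category <- ifelse(is.na(ratio), NA_character_,
                     ifelse(ratio < 86, "less than recommended",
                            ifelse(ratio > 120, "more than recommended",
                                   "recommended")))
  list(ratio = ratio, category = category)
}

#' Dichotomize a physical-activity response
#'
#' Active (1) if and only if the caretaker reported the child "active most
#' of the time"; the other responses code as inactive (0); missing
#' propagates for later imputation.
#'
#' @param raw_response Character vector of responses.
#' @return Numeric 0/1/NA.
#' @export
classify_activity <- function(raw_response) {
  allowed <- c("active most of the time", "active some of the time",
               "hardly at all")
  r <- trimws(tolower(as.character(raw_response)))
  bad <- !is.na(r) & !r %in% allowed
  if (any(bad)) stop("classify_activity: unknown response(s): ",
                     paste(unique(r[bad]), collapse = "; "))
  ifelse(is.na(r), NA_real_, as.numeric(r == "active most of the time"))
}

#' Build the outcome table from visit records
#'
#' @param visits Visit records (see \code{\link{read_visits}}).
#' @param mothers Mother records (for child sex).
#' @param lms Optional LMS reference; if supplied BMI z-scores are added.
#' @return \code{data.frame} keyed by (subject_id, visit) with
#'   \code{pct_fat}, \code{bmi} and optionally \code{bmi_z}.
#' @export
build_outcomes <- function(visits, mothers, lms = NULL) {
  out <- visits[c("subject_id", "visit", "age_months")]
  out$pct_fat <- percent_fat_mass(visits$fat_mass, visits$weight)
  out$bmi <- bmi(visits$weight, visits$height)
  if (!is.null(lms)) {
    sex <- mothers$child_sex[match(visits$subject_id, mothers$subject_id)]
    out$bmi_z <- bmi_zscore(out$bmi, sex, visits$age_months, lms)
  }
  out
}
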