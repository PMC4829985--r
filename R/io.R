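# CSV ingestion for the three study datasets.  Schemas are frozen:
#
# mothers.csv  one row per mother; columns: subject_id, one column per
#              registry metabolite code holding the concentration in ug/L or
#              the literal token "<LOD", creatinine (mg/dL), collection_date
#              (ISO-8601), race_ethnicity (white|black|hispanic),
#              maternal_age (y), education, work_status, smoking (0/1),
#              prepreg_bmi (kg/m2), maternal_height (m), first_preg_weight,
#              last_preg_weight (kg; may be empty), gestational_age (wk),
#              birth_weight (g), child_sex (1 = male), breastfed (0/1; may
#              be empty).
# visits.csv   one row per (subject, visit): subject_id, visit (1-3),
#              age_months, weight (kg), fat_mass (kg; empty if missing),
#              height (m), active (0/1; may be empty), outcome_missing (0/1).
# lms.csv      growth-reference rows: sex, age_months, L, M, S.

LOD_TOKEN <- "<LOD"

mother_covariate_cols <- function() {
  c("creatinine", "collection_date", "race_ethnicity", "maternal_age",
    "education", "work_status", "smoking", "prepreg_bmi", "maternal_height",
    "first_preg_weight", "last_preg_weight", "gestational_age",
    "birth_weight", "child_sex", "breastfed")
}

#' Read mother-level exposure and covariate records
#'
#' Concentration cells holding the literal token \code{"<LOD"} are flagged as
#' censored; the stored numeric value for such cells is the (raw) LOD
#' placeholder and is never used directly in modelling.  Records missing any
#' required covariate (anything other than \code{last_preg_weight} and
#' \code{breastfed}) are rejected with a warning.
#'
#' @param path Path to \code{mothers.csv} (schema in the package README).
#' @param registry Metabolite registry; \code{\link{default_registry}()} by
#'   default.
#' @return A \code{data.frame} with one numeric column per metabolite code, a
#'   logical censor-flag column \code{cens_<code>} per metabolite, and all
#'   covariate columns.
#' @export
read_mothers <- function(path, registry = default_registry()) {
  raw <- read_csv_plain(path)
  if (!"subject_id" %in% names(raw))
    stop("mothers schema error: missing column subject_id")
  covs <- mother_covariate_cols()
  known <- c("subject_id", registry$code, covs)
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("mothers schema error: unknown metabolite code or column: ",
         paste(extra, collapse = ", "))
  missing_cols <- setdiff(known, names(raw))
  if (length(missing_cols))
    stop("mothers schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))

  out <- data.frame(subject_id = raw$subject_id, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(registry))) {
    code <- registry$code[k]
    if (is.numeric(raw[[code]])) {       # no "<LOD" token in the column
      cens <- rep(FALSE, nrow(raw))
      val <- as.numeric(raw[[code]])
    } else {
      cell <- as.character(raw[[code]])
      cens <- !is.na(cell) & trimws(cell) == LOD_TOKEN
      val <- suppressWarnings(as.numeric(cell))
      val[cens] <- registry$lod[k]
    }
    if (any(is.na(val)))
      stop("mothers value error: non-numeric ", code,
           " concentration (and not '", LOD_TOKEN, "')")
    if (any(val[!cens] <= 0))
      stop("mothers value error: non-positive ", code, " concentration")
    out[[code]] <- val
    out[[paste0("cens_", code)]] <- cens
  }
  for (cv in covs) {
    if (cv == "race_ethnicity") {
      v <- as.character(raw[[cv]])
      bad <- !is.na(v) & !v %in% c("white", "black", "hispanic")
      if (any(bad))
        stop("mothers value error: race_ethnicity must be white|black|hispanic")
      out[[cv]] <- v
    } else if (cv == "collection_date") {
      out[[cv]] <- as.Date(as.character(raw[[cv]]))
    } else {
      out[[cv]] <- as.numeric(raw[[cv]])
    }
  }
  if (any(!is.na(out$creatinine) & out$creatinine <= 0))
    stop("mothers value error: creatinine must be > 0")
  for (bcol in c("education", "work_status", "smoking", "child_sex",
                 "breastfed")) {
    if (!is_binary01(out[[bcol]]))
      stop("mothers value error: ", bcol, " must be 0/1")
  }
  required <- setdiff(covs, c("last_preg_weight", "breastfed"))
  ok <- rep(TRUE, nrow(out))
  for (cv in required) ok <- ok & !is.na(out[[cv]])
  if (any(!ok)) {
    warning(sum(!ok), " mother record(s) rejected: required covariate missing")
    out <- out[ok, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write mother records to CSV
#'
#' Inverse of \code{\link{read_mothers}}: censored cells are emitted as the
#' token \code{"<LOD"} so the round trip is the identity.
#'
#' @param mothers Mother records as returned by \code{\link{read_mothers}} or
#'   \code{\link{simulate_mothers}}.
#' @param path Output path.
#' @param registry Metabolite registry.
#' @return \code{path}, invisibly.
#' @export
write_mothers <- function(mothers, path, registry = default_registry()) {
  out <- data.frame(subject_id = mothers$subject_id, stringsAsFactors = FALSE)
  for (code in registry$code) {
    val <- mothers[[code]]
    cens <- mothers[[paste0("cens_", code)]]
    s <- vapply(val, function(v) {
      for (d in c(15L, 16L, 17L)) {
        r <- sprintf("%.*g", d, v)
        if (as.numeric(r) == v) return(r)
      }
      r
    }, character(1))
    s[cens] <- LOD_TOKEN
    out[[code]] <- s
  }
  for (cv in mother_covariate_cols()) {
    out[[cv]] <- if (cv == "collection_date")
      format(mothers[[cv]], "%Y-%m-%d") else mothers[[cv]]
  }
  write_csv_exact(out, path)
}

#' Read child-visit outcome records
#'
#' @param path Path to \code{visits.csv}.
#' @param mothers Optional mother records; if supplied, visit rows whose
#'   \code{subject_id} has no mother record are flagged with a warning.
#' @return A \code{data.frame}, one row per (subject, visit).
#' @export
read_visits <- function(path, mothers = NULL) {
  raw <- read_csv_plain(path)
  cols <- c("subject_id", "visit", "age_months", "weight", "fat_mass",
            "height", "active", "outcome_missing")
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols))
    stop("visits schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0) {
    warning("visits file is empty")
    out <- raw[cols]
    for (cc in setdiff(cols, "subject_id")) out[[cc]] <- numeric(0)
    return(out)
  }
  out <- raw[cols]
  for (cc in setdiff(cols, "subject_id")) out[[cc]] <- as.numeric(out[[cc]])
  if (anyDuplicated(out[c("subject_id", "visit")]))
    stop("visits schema error: duplicate (subject_id, visit) row(s)")
  obs <- !is.na(out$fat_mass)
  if (any(obs & out$outcome_missing == 1))
    stop("visits consistency error: fat_mass present but outcome_missing = 1")
  if (any(!obs & out$outcome_missing == 0))
    stop("visits consistency error: fat_mass absent but outcome_missing = 0")
  if (any(obs & (out$fat_mass < 0 | out$fat_mass >= out$weight)))
    stop("visits value error: fat_mass must satisfy 0 <= fat_mass < weight")
  if (!is.null(mothers)) {
    orphan <- !out$subject_id %in% mothers$subject_id
    if (any(orphan))
      warning(sum(orphan), " visit row(s) have no mother record (orphans)")
    out$orphan <- orphan
  }
  out
}

#' Write visit records to CSV
#' @param visits Visit records.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_visits <- function(visits, path) {
  cols <- c("subject_id", "visit", "age_months", "weight", "fat_mass",
            "height", "active", "outcome_missing")
  write_csv_exact(visits[cols], path)
}

#' Read an LMS growth-reference table
#'
#' @param path CSV with columns \code{sex, age_months, L, M, S}.
#' @return Validated \code{data.frame}.
#' @export
read_lms <- function(path) {
  lms <- read_csv_plain(path)
  missing_cols <- setdiff(c("sex", "age_months", "L", "M", "S"), names(lms))
  if (length(missing_cols))
    stop("lms schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(lms$M <= 0) || any(lms$S <= 0))
    stop("lms value error: M and S must be > 0")
  lms
}
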