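#' Default phthalate metabolite registry
#'
#' The registry drives every exposure computation: limits of detection (LOD,
#' ug/L, on the raw analytical scale before correction factors), analytical
#' correction factors, molecular weights (g/mol, equivalently ug/umol) used
#' for molar sums, and the parent grouping that defines the DEHP sum.
#'
#' Correction factors adjust MBzP (0.72) and MEP (0.66) concentrations and
#' LODs for inaccuracies in early analytical standards; all other metabolites
#' carry a factor of 1.  The four oxidative/hydrolytic DEHP metabolites
#' (MECPP, MEHHP, MEHP, MEOHP) carry \code{group = "DEHP"} and are combined
#' into a molar sum; the remaining metabolites are modelled singly
#' (\code{group = "single"}).
#'
#' @return A \code{data.frame} with columns \code{code}, \code{lod},
#'   \code{correction_factor}, \code{mol_weight}, \code{group}; one row per
#'   metabolite, in the canonical column order used throughout the package.
#' @examples
#' reg <- default_registry()
#' subset(reg, group == "DEHP")
#' @export
default_registry <- function() {
  reg <- data.frame(
    code = c("MEP", "MnBP", "MiBP", "MCPP", "MBzP",
             "MECPP", "MEHHP", "MEHP", "MEOHP"),
    lod = c(0.39, 0.4, 0.26, 0.16, 0.11,
            0.25, 0.32, 0.9, 0.45),
    correction_factor = c(0.66, 1, 1, 1, 0.72, 1, 1, 1, 1),
    mol_weight = c(194.18, 222.24, 222.24, 252.22, 256.25,
                   308.33, 294.34, 278.34, 292.33),
    group = c(rep("single", 5), rep("DEHP", 4)),
    stringsAsFactors = FALSE
  )
  validate_registry(reg)
}

#' Read a metabolite registry from CSV
#'
#' @param path Path to a CSV with header
#'   \code{code,lod,correction_factor,mol_weight,group}.
#' @return Validated registry \code{data.frame} (see
#'   \code{\link{default_registry}} for the schema).
#' @export
read_registry <- function(path) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("code", "lod", "correction_factor", "mol_weight", "group")
  missing_cols <- setdiff(required, names(reg))
  if (length(missing_cols))
    stop("registry schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  validate_registry(reg[required])
}

#' Write a metabolite registry to CSV
#'
#' Floats are written with round-trip precision so write-then-read is the
#' identity.
#'
#' @param registry Registry \code{data.frame}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_registry <- function(registry, path) {
  registry <- validate_registry(registry)
  write_csv_exact(registry, path)
}

validate_registry <- function(reg) {
  stopifnot(is.data.frame(reg))
  if (anyDuplicated(reg$code))
    stop("registry schema error: duplicate metabolite code(s): ",
         paste(unique(reg$code[duplicated(reg$code)]), collapse = ", "))
  if (any(!is.finite(reg$lod)) || any(reg$lod <= 0))
    stop("registry value error: lod must be > 0")
  if (any(reg$correction_factor <= 0) || any(reg$correction_factor > 1))
    stop("registry value error: correction_factor must be in (0, 1]")
  if (any(reg$mol_weight <= 0))
    stop("registry value error: mol_weight must be > 0")
  if (!all(reg$group %in% c("single", "DEHP")))
    stop("registry value error: group must be 'single' or 'DEHP'")
  rownames(reg) <- NULL
  reg
}

dehp_codes <- function(registry) registry$code[registry$group == "DEHP"]
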