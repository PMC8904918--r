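#' Controlled vocabularies for ICSR fields
#'
#' Fixed value sets used throughout the package: report sources, sexes,
#' report/reaction outcomes, seriousness criteria and drug roles/classes.
#' Seriousness is set-valued on a report (a case may satisfy several
#' criteria); `seriousness_precedence()` gives the display order used when a
#' single label per case is needed, as in serious case series listings.
#'
#' @name vocab
NULL

#' @rdname vocab
#' @export
pv_sexes <- function() c("F", "M", "unknown")

#' @rdname vocab
#' @export
pv_sources <- function() c("spontaneous", "solicited", "literature")

#' @rdname vocab
#' @export
pv_outcomes <- function() {
  c("fully_recovered", "improved", "not_yet_recovered",
    "recovered_with_sequelae", "death", "unknown")
}

#' @rdname vocab
#' @export
pv_seriousness_criteria <- function() {
  c("death", "life_threatening", "hospitalization", "disability",
    "congenital_anomaly", "other_medically_important")
}

#' @rdname vocab
#' @export
pv_drug_roles <- function() c("suspected", "concomitant")

#' @rdname vocab
#' @export
pv_drug_classes <- function() c("immunostimulant", "immunosuppressant", "other")

#' Display precedence for seriousness criteria
#'
#' A report can satisfy several seriousness criteria; case listings print one
#' label per case. The precedence (most to least severe) is: death >
#' life-threatening > disability > congenital anomaly > hospitalization >
#' other medically important condition, mirroring the usual regulatory
#' severity ordering.
#'
#' @return Character vector of criteria, most severe first.
#' @export
seriousness_precedence <- function() {
  c("death", "life_threatening", "disability", "congenital_anomaly",
    "hospitalization", "other_medically_important")
}

#' Pick the display label for a set of seriousness criteria
#'
#' @param criteria Character vector (possibly empty) of seriousness criteria.
#' @return A single string: the highest-precedence criterion, or
#'   `"not_serious"` for an empty set.
#' @export
seriousness_label <- function(criteria) {
  criteria <- criteria[!is.na(criteria) & nzchar(criteria)]
  if (length(criteria) == 0L) return("not_serious")
  bad <- setdiff(criteria, pv_seriousness_criteria())
  if (length(bad) > 0L) {
    stop("unknown seriousness criteria: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  prec <- seriousness_precedence()
  prec[min(match(criteria, prec))]
}

#' Classify age in years into reporting age bands
#'
#' Bands follow the stratified-table convention: `<18`, `18-65` (both bounds
#' inclusive), `>=66`. Missing ages go to the `missing` band so stratified
#' counts never silently drop reports. Fractional ages between 65 and 66 are
#' assigned to the adult band (`age < 66`).
#'
#' @param age_years Numeric vector of ages in years; `NA` allowed.
#' @return Factor with levels `under_18`, `adult_18_65`, `senior_66_plus`,
#'   `missing`.
#' @examples
#' classify_age_group(c(17, 18, 65, 66, NA))
#' @export
classify_age_group <- function(age_years) {
  if (!is.numeric(age_years) && !all(is.na(age_years))) {
    stop("`age_years` must be numeric", call. = FALSE)
  }
  age_years <- as.numeric(age_years)
  bad <- which(!is.na(age_years) & (age_years < 0 | age_years > 120))
  if (length(bad) > 0L) {
    stop("age_years out of [0, 120] at position(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  lev <- c("under_18", "adult_18_65", "senior_66_plus", "missing")
  out <- rep("missing", length(age_years))
  out[!is.na(age_years) & age_years < 18] <- "under_18"
  out[!is.na(age_years) & age_years >= 18 & age_years < 66] <- "adult_18_65"
  out[!is.na(age_years) & age_years >= 66] <- "senior_66_plus"
  factor(out, levels = lev)
}
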