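#' Bundle the three relational ICSR tables into one object
#'
#' An individual case safety report (ICSR) dataset is relational: one row per
#' report, one row per drug mention, one row per reaction. `icsr_set()` keeps
#' the three tibbles together, joined on `report_id`.
#'
#' Column contracts:
#' * `reports`: `report_id`, `region`, `receipt_date` (Date), `source`
#'   (spontaneous/solicited/literature), `sex` (F/M/unknown or NA),
#'   `age_years`, `seriousness` (semicolon-joined criteria; `""` = explicitly
#'   not serious, `NA` = unknown), `outcome`, `comorbidities` (free text).
#' * `drugs`: `report_id`, `code`, `name`, `brand`, `role`
#'   (suspected/concomitant), `indication`, `start_date`, `stop_date`.
#' * `reactions`: `report_id`, `verbatim`, `pt`, `soc`, `onset_date`,
#'   `resolution_date`, `outcome`.
#'
#' @param reports,drugs,reactions Data frames as described above.
#' @return An object of class `icsr_set` (a named list of three tibbles).
#' @export
icsr_set <- function(reports, drugs, reactions) {
  reports <- tibble::as_tibble(reports)
  drugs <- tibble::as_tibble(drugs)
  reactions <- tibble::as_tibble(reactions)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0L) {
      stop(what, " table missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  need(reports, c("report_id", "receipt_date", "source", "sex", "age_years",
                  "seriousness", "outcome"), "reports")
  need(drugs, c("report_id", "code", "role"), "drugs")
  need(reactions, c("report_id", "verbatim"), "reactions")
  if (anyDuplicated(reports$report_id)) {
    stop("duplicate report_id in reports table", call. = FALSE)
  }
  for (col in c("pt", "soc")) {
    if (!col %in% names(reactions)) reactions[[col]] <- NA_character_
  }
  if (!"onset_date" %in% names(reactions)) {
    reactions$onset_date <- as.Date(NA)
  }
  if (!"resolution_date" %in% names(reactions)) {
    reactions$resolution_date <- as.Date(NA)
  }
  structure(list(reports = reports, drugs = drugs, reactions = reactions),
            class = "icsr_set")
}

#' @export
print.icsr_set <- function(x, ...) {
  cat("<icsr_set> ", nrow(x$reports), " reports, ", nrow(x$drugs),
      " drug mentions, ", nrow(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

#' Number of reports in an ICSR set
#'
#' @param x An [icsr_set()].
#' @return Integer count of reports.
#' @export
n_reports <- function(x) {
  stopifnot(inherits(x, "icsr_set"))
  nrow(x$reports)
}

# serious iff the criteria set is non-empty; NA propagates (unknown)
is_serious <- function(seriousness) {
  ifelse(is.na(seriousness), NA, nzchar(seriousness))
}

#' Normalize verbatim reaction terms to canonical PT and SOC
#'
#' Applies single-hop synonym folding, then maps each canonical PT to its
#' system organ class. Terms absent from the dictionary are handled by
#' `unknown`: `"flag"` (default) passes the verbatim term through as its own
#' PT with SOC `"Unclassified"` and marks it in the `unknown_term` column, so
#' descriptive tables never silently drop data; `"reject"` raises an error
#' naming the offending terms and report ids.
#'
#' Normalization is idempotent: re-normalizing an already-normalized set is a
#' no-op.
#'
#' @param x An [icsr_set()].
#' @param dict A [meddra_dictionary()].
#' @param unknown Unknown-term policy, `"flag"` or `"reject"`.
#' @return The input `icsr_set` with `pt`, `soc` and `unknown_term` filled in
#'   on the reactions table.
#' @export
normalize_reactions <- function(x, dict, unknown = c("flag", "reject")) {
  stopifnot(inherits(x, "icsr_set"))
  unknown <- match.arg(unknown)
  rx <- x$reactions
  # re-normalization resolves from the existing pt when present, else verbatim
  base_term <- ifelse(!is.na(rx$pt), rx$pt, rx$verbatim)
  pt <- canonical_pt(base_term, dict)
  soc <- pt_soc(pt, dict)
  unknown_term <- is.na(soc)
  if (unknown == "reject" && any(unknown_term)) {
    bad <- unique(paste0("'", pt[unknown_term], "' (report ",
                         rx$report_id[unknown_term], ")"))
    stop("unknown reaction term(s): ",
         paste(utils::head(bad, 10), collapse = "; "), call. = FALSE)
  }
  soc[unknown_term] <- "Unclassified"
  rx$pt <- pt
  rx$soc <- soc
  rx$unknown_term <- unknown_term
  x$reactions <- rx
  x
}

#' Validate an ICSR set against the data-model invariants
#'
#' Violations are data, not exceptions: each failed rule yields one row naming
#' the report, the field, and the rule, so a whole batch can be audited in one
#' pass.
#'
#' Checked rules: every report has at least one suspected drug and at least
#' one reaction; `age_years` (when present) lies in \[0, 120\]; `sex`,
#' `source` and `outcome` use the controlled vocabularies; drug
#' `start_date <= stop_date` and reaction `onset_date <= resolution_date`
#' when both present; seriousness criteria belong to the controlled set.
#'
#' @param x An [icsr_set()].
#' @return Tibble with columns `report_id`, `field`, `rule`; zero rows iff
#'   all invariants hold.
#' @export
validate_icsr <- function(x) {
  stopifnot(inherits(x, "icsr_set"))
  rp <- x$reports
  v <- list()
  add <- function(ids, field, rule) {
    if (length(ids) > 0L) {
      v[[length(v) + 1L]] <<- tibble::tibble(report_id = ids, field = field,
                                             rule = rule)
    }
  }

  suspected_ids <- unique(x$drugs$report_id[x$drugs$role == "suspected"])
  add(setdiff(rp$report_id, suspected_ids), "drugs", "no suspected drug")
  add(setdiff(rp$report_id, unique(x$reactions$report_id)), "reactions",
      "no reaction")
  add(rp$report_id[!is.na(rp$age_years) &
                     (rp$age_years < 0 | rp$age_years > 120)],
      "age_years", "age outside [0, 120]")
  add(rp$report_id[!is.na(rp$sex) & !rp$sex %in% pv_sexes()],
      "sex", "sex not in {F, M, unknown}")
  add(rp$report_id[!is.na(rp$source) & !rp$source %in% pv_sources()],
      "source", "unknown report source")
  add(rp$report_id[!is.na(rp$outcome) & !rp$outcome %in% pv_outcomes()],
      "outcome", "unknown outcome")
  crit_ok <- vapply(split_seriousness(rp$seriousness), function(s) {
    all(s %in% pv_seriousness_criteria())
  }, logical(1))
  add(rp$report_id[!crit_ok], "seriousness", "unknown seriousness criterion")

  dg <- x$drugs
  bad_dates <- !is.na(dg$start_date) & !is.na(dg$stop_date) &
    dg$start_date > dg$stop_date
  add(dg$report_id[bad_dates], "drug dates", "start_date after stop_date")
  add(dg$report_id[!is.na(dg$role) & !dg$role %in% pv_drug_roles()],
      "role", "unknown drug role")

  rx <- x$reactions
  bad_rx <- !is.na(rx$onset_date) & !is.na(rx$resolution_date) &
    rx$onset_date > rx$resolution_date
  add(rx$report_id[bad_rx], "reaction dates",
      "onset_date after resolution_date")

  if (length(v) == 0L) {
    tibble::tibble(report_id = character(), field = character(),
                   rule = character())
  } else {
    dplyr::distinct(dplyr::bind_rows(v))
  }
}
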