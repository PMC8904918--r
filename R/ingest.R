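#' Read an ICSR dataset from the three-table CSV dialect
#'
#' Reads `reports.csv`, `drugs.csv` and `reactions.csv` (columns documented in
#' [icsr_set()]), parses all dates strictly as ISO-8601, and reconciles the
#' row counts: drug or reaction rows whose `report_id` has no matching report
#' ("orphans") abort the load unless `allow_orphans = TRUE`, in which case
#' they are dropped and listed in the parse log.
#'
#' @param reports_path,drugs_path,reactions_path CSV file paths.
#' @param allow_orphans Keep going when orphan rows are found?
#' @return An [icsr_set()]; the parse log (row counts and orphan listing) is
#'   attached as attribute `"log"`.
#' @export
read_icsr <- function(reports_path, drugs_path, reactions_path,
                      allow_orphans = FALSE) {
  # "" and NA are distinct in the seriousness field (explicitly not serious
  # vs unknown), so only the literal string NA is read as missing there;
  # every other character field treats blanks as missing as usual
  read_chr <- function(path) {
    df <- readr::read_csv(path,
                          col_types = readr::cols(.default = readr::col_character()),
                          na = "NA", progress = FALSE)
    for (col in setdiff(names(df), "seriousness")) {
      df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
    }
    df
  }
  rp <- read_chr(reports_path)
  dg <- read_chr(drugs_path)
  rx <- read_chr(reactions_path)

  need <- function(df, cols, path) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0L) {
      stop(basename(path), " missing required column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  need(rp, c("report_id", "receipt_date", "source", "sex", "age_years",
             "seriousness", "outcome"), reports_path)
  need(dg, c("report_id", "code", "role"), drugs_path)
  need(rx, c("report_id", "verbatim"), reactions_path)

  rp$receipt_date <- parse_iso_date(rp$receipt_date, "receipt_date")
  rp$age_years <- suppressWarnings(as.numeric(rp$age_years))
  if (!"region" %in% names(rp)) rp$region <- NA_character_
  if (!"comorbidities" %in% names(rp)) rp$comorbidities <- NA_character_
  for (col in c("name", "brand", "indication")) {
    if (!col %in% names(dg)) dg[[col]] <- NA_character_
  }
  dg$start_date <- parse_iso_date(dg$start_date %||% NA_character_, "start_date")
  dg$stop_date <- parse_iso_date(dg$stop_date %||% NA_character_, "stop_date")
  rx$onset_date <- parse_iso_date(rx$onset_date %||% NA_character_, "onset_date")
  rx$resolution_date <- parse_iso_date(rx$resolution_date %||% NA_character_,
                                       "resolution_date")
  if (!"outcome" %in% names(rx)) rx$outcome <- NA_character_

  orphans <- dplyr::bind_rows(
    tibble::tibble(table = "drugs",
                   report_id = setdiff(dg$report_id, rp$report_id)),
    tibble::tibble(table = "reactions",
                   report_id = setdiff(rx$report_id, rp$report_id))
  )
  if (nrow(orphans) > 0L && !allow_orphans) {
    stop("orphan rows reference unknown report_id(s): ",
         paste(utils::head(unique(orphans$report_id), 10), collapse = ", "),
         " (use allow_orphans = TRUE to drop them)", call. = FALSE)
  }
  dg <- dg[dg$report_id %in% rp$report_id, ]
  rx <- rx[rx$report_id %in% rp$report_id, ]

  out <- icsr_set(rp, dg, rx)
  attr(out, "log") <- list(
    n_reports = nrow(rp), n_drug_rows = nrow(dg), n_reaction_rows = nrow(rx),
    n_orphans = nrow(orphans), orphans = orphans
  )
  out
}

#' Write an ICSR set back to the three-table CSV dialect
#'
#' @param x An [icsr_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths written.
#' @export
write_icsr <- function(x, dir) {
  stopifnot(inherits(x, "icsr_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("reports.csv", "drugs.csv", "reactions.csv"))
  keep <- intersect(c("report_id", "region", "receipt_date", "source", "sex",
                      "age_years", "seriousness", "outcome", "comorbidities"),
                    names(x$reports))
  readr::write_csv(x$reports[keep], paths[1], progress = FALSE)
  readr::write_csv(x$drugs, paths[2], progress = FALSE)
  keep_rx <- intersect(c("report_id", "verbatim", "onset_date",
                         "resolution_date", "outcome"), names(x$reactions))
  readr::write_csv(x$reactions[keep_rx], paths[3], progress = FALSE)
  invisible(paths)
}

#' Study inclusion configuration
#'
#' Defines the report-level inclusion rules: the reporting window, the
#' qualifying suspected-drug codes, per-drug brand restrictions (e.g. a drug
#' in scope only under its MS-indicated brand), report sources to exclude
#' (e.g. literature reports), and an optional region filter.
#'
#' @param window_start,window_end Dates (or ISO strings) bounding receipt
#'   dates, inclusive.
#' @param suspected_drug_codes Character vector of qualifying drug codes.
#' @param brand_restrictions Named character vector: drug code -> required
#'   brand. Keys must be a subset of `suspected_drug_codes`.
#' @param exclude_sources Report sources to drop (default: literature).
#' @param region_filter Optional region string; reports from other regions
#'   are excluded.
#' @return An object of class `inclusion_config`.
#' @export
inclusion_config <- function(window_start, window_end, suspected_drug_codes,
                             brand_restrictions = c(L04AA40 = "Mavenclad"),
                             exclude_sources = "literature",
                             region_filter = NULL) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  stopifnot(window_start <= window_end)
  if (length(brand_restrictions) > 0L) {
    stopifnot(!is.null(names(brand_restrictions)))
    extra <- setdiff(names(brand_restrictions), suspected_drug_codes)
    if (length(extra) > 0L) {
      stop("brand_restrictions keys not in suspected_drug_codes: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  stopifnot(all(exclude_sources %in% pv_sources()))
  structure(list(window_start = window_start, window_end = window_end,
                 suspected_drug_codes = suspected_drug_codes,
                 brand_restrictions = brand_restrictions,
                 exclude_sources = exclude_sources,
                 region_filter = region_filter),
            class = "inclusion_config")
}

#' Default study configuration for the MS drug surveillance window
#'
#' Reporting window January 2002 through December 2020, the eleven MS
#' disease-modifying therapies as qualifying suspected drugs, cladribine
#' restricted to its MS brand, and literature reports excluded.
#'
#' @param region_filter Optional region string.
#' @return An [inclusion_config()].
#' @export
ms_study_config <- function(region_filter = NULL) {
  inclusion_config(
    window_start = "2002-01-01", window_end = "2020-12-31",
    suspected_drug_codes = ms_drug_dictionary()$code,
    brand_restrictions = c(L04AA40 = "Mavenclad"),
    exclude_sources = "literature",
    region_filter = region_filter
  )
}

# subset all three tables to a set of report ids, preserving order of `ids`
filter_icsr <- function(x, ids) {
  out <- icsr_set(
    x$reports[match(ids, x$reports$report_id), , drop = FALSE],
    x$drugs[x$drugs$report_id %in% ids, , drop = FALSE],
    x$reactions[x$reactions$report_id %in% ids, , drop = FALSE]
  )
  out
}

#' Apply the study inclusion rules
#'
#' Splits the dataset into kept reports and excluded reports, each exclusion
#' carrying exactly one primary reason. Reasons are assigned with fixed
#' precedence so the accounting is deterministic:
#' `out_of_region` (when a region filter is set) then `out_of_window` then
#' `no_qualifying_suspected_drug` then `brand_restriction` then
#' `source_excluded`. A report passes the drug rule when at least one
#' suspected drug is in the qualifying code set; among those, the brand rule
#' requires at least one qualifying suspected drug whose brand restriction
#' (if any) is satisfied. Counts are conserved:
#' `n(kept) + n(excluded) = n(input)`.
#'
#' @param x An [icsr_set()].
#' @param cfg An [inclusion_config()].
#' @return List with elements `kept` (an `icsr_set`) and `excluded` (tibble
#'   `report_id`, `reason`).
#' @export
apply_inclusion <- function(x, cfg) {
  stopifnot(inherits(x, "icsr_set"), inherits(cfg, "inclusion_config"))
  rp <- x$reports
  sus <- x$drugs[x$drugs$role == "suspected", c("report_id", "code", "brand")]
  sus <- sus[sus$code %in% cfg$suspected_drug_codes, , drop = FALSE]
  restr <- cfg$brand_restrictions
  brand_ok <- rep(TRUE, nrow(sus))
  if (length(restr) > 0L) {
    i <- match(sus$code, names(restr))
    has_restr <- !is.na(i)
    brand_ok[has_restr] <- !is.na(sus$brand[has_restr]) &
      sus$brand[has_restr] == restr[i[has_restr]]
  }
  has_qualifying <- rp$report_id %in% sus$report_id
  passes_brand <- rp$report_id %in% sus$report_id[brand_ok]

  reason <- rep(NA_character_, nrow(rp))
  if (!is.null(cfg$region_filter)) {
    out_region <- is.na(rp$region) | rp$region != cfg$region_filter
    reason[is.na(reason) & out_region] <- "out_of_region"
  }
  out_window <- is.na(rp$receipt_date) |
    rp$receipt_date < cfg$window_start | rp$receipt_date > cfg$window_end
  reason[is.na(reason) & out_window] <- "out_of_window"
  reason[is.na(reason) & !has_qualifying] <- "no_qualifying_suspected_drug"
  reason[is.na(reason) & !passes_brand] <- "brand_restriction"
  reason[is.na(reason) & rp$source %in% cfg$exclude_sources] <-
    "source_excluded"

  kept_ids <- rp$report_id[is.na(reason)]
  excluded <- tibble::tibble(report_id = rp$report_id[!is.na(reason)],
                             reason = reason[!is.na(reason)])
  list(kept = filter_icsr(x, kept_ids), excluded = excluded)
}

# deterministic dedup key per report
dedup_keys <- function(x, dict = NULL) {
  sus <- x$drugs[x$drugs$role == "suspected", c("report_id", "code")]
  drug_key <- vapply(split(sus$code, sus$report_id),
                     function(v) paste(sort(unique(v)), collapse = "|"),
                     character(1))
  rx <- x$reactions
  term <- ifelse(!is.na(rx$pt), rx$pt, rx$verbatim)
  if (!is.null(dict)) term <- canonical_pt(term, dict)
  pt_key <- vapply(split(term, rx$report_id),
                   function(v) paste(sort(unique(v)), collapse = "|"),
                   character(1))
  onset_key <- vapply(split(rx$onset_date, rx$report_id), function(d) {
    d <- d[!is.na(d)]
    if (length(d) == 0L) "" else as.character(min(d))
  }, character(1))
  rp <- x$reports
  lookup <- function(keys) {
    v <- unname(keys[rp$report_id])
    v[is.na(v)] <- ""
    v
  }
  paste(
    ifelse(is.na(rp$sex), "?", rp$sex),
    ifelse(is.na(rp$age_years), "?", as.character(round(rp$age_years))),
    lookup(drug_key), lookup(pt_key), lookup(onset_key),
    sep = "~"
  )
}

#' Collapse duplicate reports
#'
#' Duplicate detection uses the standard spontaneous-reporting heuristic key:
#' (sex, rounded age, sorted suspected drug codes, sorted canonical reaction
#' terms, earliest reaction onset date). Within each key group the report
#' with the earliest receipt date is kept (ties broken by lexicographic
#' `report_id`). Idempotent: running it on its own output changes nothing.
#'
#' @param x An [icsr_set()].
#' @param dict Optional [meddra_dictionary()] used to canonicalize reaction
#'   terms before keying.
#' @return List with elements `unique` (an `icsr_set`) and `duplicates`
#'   (tibble `report_id`, `kept_id`, `key` for each dropped report).
#' @export
deduplicate_reports <- function(x, dict = NULL) {
  stopifnot(inherits(x, "icsr_set"))
  rp <- x$reports
  key <- dedup_keys(x, dict)
  ord <- order(key, rp$receipt_date, rp$report_id)
  first_of_key <- !duplicated(key[ord])
  keep_sorted <- rp$report_id[ord][first_of_key]
  kept_ids <- rp$report_id[rp$report_id %in% keep_sorted]

  # map each report to the kept representative of its key group
  keep_by_key <- stats::setNames(rp$report_id[ord][first_of_key],
                                 key[ord][first_of_key])
  dropped <- setdiff(rp$report_id, kept_ids)
  duplicates <- tibble::tibble(
    report_id = dropped,
    kept_id = unname(keep_by_key[key[match(dropped, rp$report_id)]]),
    key = key[match(dropped, rp$report_id)]
  )
  list(unique = filter_icsr(x, kept_ids), duplicates = duplicates)
}
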