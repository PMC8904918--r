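#' Type-7 quantile (linear interpolation on sorted values)
#'
#' Quantile by linear interpolation at rank `h = (n - 1) * p + 1` on the
#' sorted values — R's default (type 7). This is the convention under which
#' the package's median/IQR summaries are computed; it is pinned by the
#' serious-case-series age summary, which reproduces the printed
#' median (Q1–Q3) only under this interpolation rule.
#'
#' @param values Numeric vector; `NA`s are dropped.
#' @param p Probability (or vector of probabilities) in \[0, 1\].
#' @return Numeric vector of quantiles, one per `p`.
#' @export
quantile_type7 <- function(values, p) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no non-missing values", call. = FALSE)
  stopifnot(all(p >= 0 & p <= 1))
  unname(stats::quantile(values, probs = p, type = 7, names = FALSE))
}

#' Median and interquartile range as a one-row tibble
#'
#' @param values Numeric vector; `NA`s are dropped.
#' @return Tibble with columns `n`, `q1`, `median`, `q3`; zero rows when no
#'   non-missing value exists.
#' @export
quantile_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    return(tibble::tibble(n = integer(), q1 = numeric(), median = numeric(),
                          q3 = numeric()))
  }
  q <- quantile_type7(values, c(0.25, 0.5, 0.75))
  tibble::tibble(n = length(values), q1 = q[1], median = q[2], q3 = q[3])
}

#' 95% confidence interval for a proportion
#'
#' Wilson score interval by default (well-behaved at the boundaries and for
#' small counts); the plain normal approximation is available behind
#' `method = "normal"`.
#'
#' @param k Successes (vectorized).
#' @param n Trials (vectorized, `>= 1`).
#' @param method `"wilson"` (default) or `"normal"`.
#' @param conf_level Confidence level, default 0.95.
#' @return Tibble with columns `k`, `n`, `p`, `lower`, `upper`.
#' @export
proportion_ci <- function(k, n, method = c("wilson", "normal"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(k < 0 | k > n)) stop("k must be in [0, n]", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  if (method == "wilson") {
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lower <- centre - half
    upper <- centre + half
  } else {
    half <- z * sqrt(p * (1 - p) / n)
    lower <- p - half
    upper <- p + half
  }
  tibble::tibble(k = k, n = n, p = p,
                 lower = pmax(0, lower), upper = pmin(1, upper))
}

# one row per report: the drug row label it contributes to. Reports whose
# qualifying suspected drugs are >1 distinct codes form a combined row, the
# convention used for dual-suspect reports in stratified tables.
report_drug_rows <- function(x) {
  sus <- x$drugs[x$drugs$role == "suspected", c("report_id", "code")]
  by_report <- split(sus$code, sus$report_id)
  lab <- vapply(by_report, function(v) {
    v <- sort(unique(v))
    if (length(v) == 1L) v else "multiple_suspected"
  }, character(1))
  tibble::tibble(report_id = names(lab), drug = unname(lab))
}

#' Stratified count table (counts and percentages by drug)
#'
#' One block of the classic descriptive table: reports stratified by
#' seriousness, sex, age group or outcome, with one row per suspected drug
#' (dual-suspect reports form a combined `multiple_suspected` row, so each
#' report is counted exactly once) plus a `Total` row. Missing values land in
#' the explicit `missing` level; a report is classed serious iff its
#' seriousness criteria set is non-empty. Percentages are computed from the
#' counts over the row total and rounded half-up to one decimal.
#'
#' @param x An [icsr_set()].
#' @param stratum One of `"seriousness"`, `"sex"`, `"age_group"`,
#'   `"outcome"`.
#' @return Tibble with columns `drug`, `total`, `level`, `n`, `pct`. Within
#'   each drug, the `n` values sum exactly to `total`.
#' @export
stratified_counts <- function(x, stratum = c("seriousness", "sex",
                                             "age_group", "outcome")) {
  stopifnot(inherits(x, "icsr_set"))
  stratum <- match.arg(stratum)
  rp <- x$reports
  if (nrow(rp) == 0L) {
    return(tibble::tibble(drug = character(), total = integer(),
                          level = character(), n = integer(), pct = numeric()))
  }
  value <- switch(
    stratum,
    seriousness = {
      s <- is_serious(rp$seriousness)
      factor(ifelse(is.na(s), "missing",
                    ifelse(s, "serious", "not_serious")),
             levels = c("serious", "not_serious", "missing"))
    },
    sex = factor(ifelse(is.na(rp$sex) | rp$sex == "unknown", "missing",
                        rp$sex),
                 levels = c("F", "M", "missing")),
    age_group = classify_age_group(rp$age_years),
    outcome = factor(ifelse(is.na(rp$outcome), "missing", rp$outcome),
                     levels = c(pv_outcomes(), "missing"))
  )
  rows <- report_drug_rows(x)
  df <- tibble::tibble(report_id = rp$report_id, level = value) |>
    dplyr::left_join(rows, by = "report_id")
  df$drug[is.na(df$drug)] <- "no_suspected_drug"
  per_drug <- df |>
    dplyr::count(.data$drug, .data$level, .drop = FALSE, name = "n")
  total_row <- df |>
    dplyr::count(.data$level, .drop = FALSE, name = "n") |>
    dplyr::mutate(drug = "Total")
  out <- dplyr::bind_rows(per_drug, total_row) |>
    dplyr::group_by(.data$drug) |>
    dplyr::mutate(total = sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(level = as.character(.data$level),
                  pct = ifelse(.data$total > 0,
                               round_half_up(.data$n / .data$total * 100, 1),
                               0)) |>
    dplyr::select("drug", "total", "level", "n", "pct")
  out
}

#' Annual report counts
#'
#' Counts reports per receipt year. Years inside `window` with no reports
#' appear as explicit zeros, so a 2002–2020 study window always yields 19
#' rows (per drug when `by_drug = TRUE`).
#'
#' @param x An [icsr_set()].
#' @param window Length-2 vector of dates (or ISO strings) bounding the study
#'   window; default spans the observed receipt dates.
#' @param by_drug Split counts by suspected-drug row label?
#' @return Tibble with columns `year`, `n` (and `drug` when `by_drug`).
#' @export
annual_trend <- function(x, window = NULL, by_drug = FALSE) {
  stopifnot(inherits(x, "icsr_set"))
  rp <- x$reports
  yr <- as.integer(format(rp$receipt_date, "%Y"))
  if (is.null(window)) {
    if (nrow(rp) == 0L) stop("empty dataset and no window given", call. = FALSE)
    years <- seq(min(yr, na.rm = TRUE), max(yr, na.rm = TRUE))
  } else {
    window <- as.Date(window)
    years <- seq(as.integer(format(window[1], "%Y")),
                 as.integer(format(window[2], "%Y")))
  }
  if (!by_drug) {
    counts <- table(factor(yr, levels = years))
    return(tibble::tibble(year = years, n = as.integer(counts)))
  }
  rows <- report_drug_rows(x)
  df <- tibble::tibble(report_id = rp$report_id, year = yr) |>
    dplyr::left_join(rows, by = "report_id")
  tidyr::expand_grid(drug = sort(unique(df$drug)), year = years) |>
    dplyr::left_join(dplyr::count(df, .data$drug, .data$year, name = "n"),
                     by = c("drug", "year")) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
}

#' SOC / PT reaction profile for one drug
#'
#' For the reports on which the drug is suspected: each system organ class is
#' counted once per report (a report with two PTs in the same SOC increments
#' that SOC once), and each preferred term is counted once per report per
#' term. Percentages are over the drug's report total, so SOC percentages
#' never exceed 100 while PT percentages within a SOC may sum above the SOC's
#' own percentage.
#'
#' @param x An [icsr_set()] with normalized reactions.
#' @param drug_code Drug code to profile.
#' @param drug_dict Drug dictionary used to validate `drug_code`; default
#'   [ms_drug_dictionary()].
#' @return Tibble with columns `level` (`"soc"` or `"pt"`), `soc`, `pt`
#'   (`NA` on SOC rows), `n`, `pct`, plus attribute `"n_reports"` (the
#'   drug's report total).
#' @export
soc_pt_profile <- function(x, drug_code, drug_dict = ms_drug_dictionary()) {
  stopifnot(inherits(x, "icsr_set"))
  if (!drug_code %in% drug_dict$code) {
    stop("unknown drug code: ", drug_code, call. = FALSE)
  }
  ids <- unique(x$drugs$report_id[x$drugs$role == "suspected" &
                                    x$drugs$code == drug_code])
  rx <- x$reactions[x$reactions$report_id %in% ids, , drop = FALSE]
  n_drug <- length(ids)
  if (n_drug == 0L || nrow(rx) == 0L) {
    out <- tibble::tibble(level = character(), soc = character(),
                          pt = character(), n = integer(), pct = numeric())
    attr(out, "n_reports") <- n_drug
    return(out)
  }
  if (all(is.na(rx$pt))) {
    stop("reactions are not normalized; run normalize_reactions() first",
         call. = FALSE)
  }
  soc_counts <- rx |>
    dplyr::distinct(.data$report_id, .data$soc) |>
    dplyr::count(.data$soc, name = "n") |>
    dplyr::mutate(level = "soc", pt = NA_character_)
  pt_counts <- rx |>
    dplyr::distinct(.data$report_id, .data$soc, .data$pt) |>
    dplyr::count(.data$soc, .data$pt, name = "n") |>
    dplyr::mutate(level = "pt")
  out <- dplyr::bind_rows(soc_counts, pt_counts) |>
    dplyr::mutate(pct = round_half_up(.data$n / n_drug * 100, 1)) |>
    dplyr::arrange(.data$soc, .data$level != "soc",
                   dplyr::desc(.data$n)) |>
    dplyr::select("level", "soc", "pt", "n", "pct")
  attr(out, "n_reports") <- n_drug
  out
}
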