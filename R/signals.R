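#' Is a drug-event pair expected under the label registry?
#'
#' @param drug_code Character vector of drug codes; every code must be
#'   covered by the registry (explicit registry coverage is forced — an
#'   absent drug is an error, not "unexpected").
#' @param pt Character vector of preferred terms (recycled against
#'   `drug_code`).
#' @param registry An [smpc_registry()].
#' @param dict Optional [meddra_dictionary()]; when given, `pt` is synonym-
#'   canonicalized before lookup.
#' @return Logical vector: `TRUE` iff the canonical PT is in the drug's
#'   expected set.
#' @export
is_expected <- function(drug_code, pt, registry, dict = NULL) {
  stopifnot(inherits(registry, "smpc_registry"))
  absent <- setdiff(unique(drug_code), names(registry$expected))
  if (length(absent) > 0L) {
    stop("drug(s) absent from the SmPC registry: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (!is.null(dict)) pt <- canonical_pt(pt, dict)
  mapply(function(d, p) p %in% registry$expected[[d]], drug_code, pt,
         USE.NAMES = FALSE)
}

#' Build the 2x2 report-level contingency table for a drug-event pair
#'
#' The unit of counting is the report. Exposure means the drug is *suspected*
#' on the report (concomitants do not count); event presence means any
#' reaction with the given canonical PT. The four cells partition the
#' reference set: `a` drug & event, `b` drug without event, `c` event without
#' drug, `d` neither. Reports with several suspected drugs contribute to each
#' drug's exposed margin.
#'
#' @param x An [icsr_set()] — the reference report set (normalized,
#'   deduplicated).
#' @param drug_code Drug code.
#' @param pt Canonical preferred term.
#' @return One-row tibble `drug`, `pt`, `a`, `b`, `c`, `d`, `n_ref`.
#' @export
build_contingency <- function(x, drug_code, pt) {
  stopifnot(inherits(x, "icsr_set"))
  if (nrow(x$reports) == 0L) stop("empty reference set", call. = FALSE)
  ids <- x$reports$report_id
  exposed_ids <- unique(x$drugs$report_id[x$drugs$role == "suspected" &
                                            x$drugs$code == drug_code])
  event_ids <- unique(x$reactions$report_id[!is.na(x$reactions$pt) &
                                              x$reactions$pt == pt])
  exposed <- ids %in% exposed_ids
  event <- ids %in% event_ids
  tibble::tibble(
    drug = drug_code, pt = pt,
    a = sum(exposed & event), b = sum(exposed & !event),
    c = sum(!exposed & event), d = sum(!exposed & !event),
    n_ref = length(ids)
  )
}

#' Contingency tables for every observed drug-event pair
#'
#' One row per (suspected drug, canonical PT) pair that co-occurs on at
#' least one report, with the full 2x2 cells against the reference set.
#' This is the screening substrate: feed it to [ror_woolf()] to estimate
#' all pairs at once.
#'
#' @param x An [icsr_set()] with normalized reactions.
#' @return Tibble `drug`, `pt`, `a`, `b`, `c`, `d`, `n_ref`.
#' @export
pair_contingencies <- function(x) {
  stopifnot(inherits(x, "icsr_set"))
  if (nrow(x$reports) == 0L) stop("empty reference set", call. = FALSE)
  contingency_all_pairs(x)
}

# all (suspected drug, PT) pairs with a >= 1, computed in one pass
contingency_all_pairs <- function(x) {
  ids <- x$reports$report_id
  n <- length(ids)
  expo <- dplyr::distinct(
    x$drugs[x$drugs$role == "suspected", c("report_id", "code")])
  ev <- x$reactions[!is.na(x$reactions$pt), c("report_id", "pt")]
  ev <- dplyr::distinct(ev)
  n_drug <- dplyr::count(expo, .data$code, name = "n_exposed")
  n_event <- dplyr::count(ev, .data$pt, name = "n_event")
  pairs <- dplyr::inner_join(expo, ev, by = "report_id",
                             relationship = "many-to-many") |>
    dplyr::count(.data$code, .data$pt, name = "a")
  pairs |>
    dplyr::left_join(n_drug, by = "code") |>
    dplyr::left_join(n_event, by = "pt") |>
    dplyr::mutate(b = .data$n_exposed - .data$a,
                  c = .data$n_event - .data$a,
                  d = n - .data$a - .data$b - .data$c,
                  n_ref = n) |>
    dplyr::select(drug = "code", "pt", "a", "b", "c", "d", "n_ref")
}

#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' `ROR = (a d) / (b c)`; the CI is the Woolf (log-normal) interval
#' `exp(log ROR +/- z sqrt(1/a + 1/b + 1/c + 1/d))` with `z = 1.96` fixed
#' (95%). A pair is `eligible` for signal reporting when `a >= min_cases`
#' (the minimum-case rule). With any zero cell the estimate is reported as
#' indeterminate (`NA` with `indeterminate = TRUE`) rather than silently
#' corrected; the Haldane–Anscombe +0.5-to-every-cell correction is available
#' behind `haldane = TRUE`.
#'
#' @param tab Data frame with integer columns `a`, `b`, `c`, `d` (one row per
#'   drug–event pair; extra columns pass through).
#' @param min_cases Minimum `a` for eligibility (default 3).
#' @param haldane Apply the +0.5 correction to zero-cell tables?
#' @return The input tibble with `n_cases`, `ror`, `ci_low`, `ci_high`,
#'   `eligible`, `indeterminate` appended.
#' @export
ror_woolf <- function(tab, min_cases = 3, haldane = FALSE) {
  tab <- tibble::as_tibble(tab)
  stopifnot(all(c("a", "b", "c", "d") %in% names(tab)))
  a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  if (any(c(a, b, c, d) < 0)) stop("negative cell count", call. = FALSE)
  zero <- (a == 0 | b == 0 | c == 0 | d == 0)
  if (haldane) {
    a <- a + 0.5 * zero; b <- b + 0.5 * zero
    c <- c + 0.5 * zero; d <- d + 0.5 * zero
    indeterminate <- rep(FALSE, length(a))
  } else {
    indeterminate <- zero
  }
  z <- 1.96
  log_ror <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror <- exp(log_ror)
  lo <- exp(log_ror - z * se)
  hi <- exp(log_ror + z * se)
  ror[indeterminate] <- NA_real_
  lo[indeterminate] <- NA_real_
  hi[indeterminate] <- NA_real_
  tab$n_cases <- tab$a
  tab$ror <- ror
  tab$ci_low <- lo
  tab$ci_high <- hi
  tab$eligible <- tab$a >= min_cases
  tab$indeterminate <- indeterminate
  tab
}

#' Recover the point ROR from a Woolf confidence interval
#'
#' The Woolf interval is log-symmetric about the point estimate, so the
#' geometric mean of its bounds recovers the ROR:
#' `exp((log ci_low + log ci_high) / 2)`. Useful for validating printed
#' ROR/CI triples.
#'
#' @param ci_low,ci_high Positive CI bounds with `ci_low <= ci_high`.
#' @return Numeric vector of point RORs.
#' @export
ror_from_ci <- function(ci_low, ci_high) {
  if (any(ci_low <= 0 | ci_high <= 0)) {
    stop("CI bounds must be positive", call. = FALSE)
  }
  if (any(ci_low > ci_high)) stop("ci_low must be <= ci_high", call. = FALSE)
  exp((log(ci_low) + log(ci_high)) / 2)
}

#' Screen all drug-event pairs for unexpected disproportionality signals
#'
#' Iterates every (suspected drug, canonical PT) pair present in the
#' reference set, computes the 2x2 and Woolf-CI ROR, checks expectedness
#' against the label registry, and emits only pairs that are unexpected and
#' have at least `min_cases` co-reports. The reference set is the in-scope
#' report set itself, so the implicit comparator is "the other drugs in the
#' same analysis stratum".
#'
#' @param x An [icsr_set()] — normalized, deduplicated reference set.
#' @param registry An [smpc_registry()] covering every suspected drug in the
#'   data.
#' @param dict Optional dictionary for PT canonicalization in the
#'   expectedness check.
#' @param min_cases Minimum case count (default 3).
#' @param haldane Passed to [ror_woolf()].
#' @return A tibble of class `pv_screen`, sorted by descending ROR, with
#'   columns `drug`, `pt`, `a`..`d`, `n_ref`, `n_cases`, `ror`, `ci_low`,
#'   `ci_high`, `eligible`, `indeterminate`, `expected`, `report_ids`
#'   (list-column of supporting reports).
#' @export
screen_signals <- function(x, registry, dict = NULL, min_cases = 3,
                           haldane = FALSE) {
  stopifnot(inherits(x, "icsr_set"))
  pairs <- contingency_all_pairs(x)
  if (nrow(pairs) == 0L) {
    out <- tibble::tibble()
    class(out) <- c("pv_screen", class(out))
    return(out)
  }
  pairs$expected <- is_expected(pairs$drug, pairs$pt, registry, dict)
  res <- ror_woolf(pairs, min_cases = min_cases, haldane = haldane)
  res <- res[!res$expected & res$eligible, , drop = FALSE]
  res <- res[order(-ifelse(is.na(res$ror), -Inf, res$ror)), , drop = FALSE]
  # supporting reports: drug suspected AND event present
  expo <- dplyr::distinct(
    x$drugs[x$drugs$role == "suspected", c("report_id", "code")])
  ev <- dplyr::distinct(
    x$reactions[!is.na(x$reactions$pt), c("report_id", "pt")])
  both <- dplyr::inner_join(expo, ev, by = "report_id",
                            relationship = "many-to-many")
  res$report_ids <- purrr::map2(res$drug, res$pt, function(d, p) {
    sort(both$report_id[both$code == d & both$pt == p])
  })
  attr(res, "n_ref") <- n_reports(x)
  attr(res, "n_pairs_tested") <- nrow(pairs)
  class(res) <- c("pv_screen", class(res))
  res
}

#' @export
print.pv_screen <- function(x, ...) {
  cat("<pv_screen> ", nrow(x), " unexpected signal(s) among ",
      attr(x, "n_pairs_tested") %||% NA, " drug-event pairs (reference set n = ",
      attr(x, "n_ref") %||% NA, ")\n", sep = "")
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a signal screen into a plain per-pair tibble
#'
#' @param x A `pv_screen` from [screen_signals()].
#' @param ... Unused.
#' @return Tibble with one row per emitted signal: `drug`, `pt`, `n_cases`,
#'   `ror`, `ci_low`, `ci_high` (estimates rounded to one decimal for
#'   display parity with printed tables is left to the caller).
#' @export
tidy.pv_screen <- function(x, ...) {
  tibble::as_tibble(x)[, c("drug", "pt", "n_cases", "ror", "ci_low",
                           "ci_high", "expected")]
}

#' One-row summary of a signal screen
#'
#' @param x A `pv_screen` from [screen_signals()].
#' @param ... Unused.
#' @return Tibble with `n_ref`, `n_pairs_tested`, `n_signals`, `max_ror`.
#' @export
glance.pv_screen <- function(x, ...) {
  tibble::tibble(
    n_ref = attr(x, "n_ref") %||% NA_integer_,
    n_pairs_tested = attr(x, "n_pairs_tested") %||% NA_integer_,
    n_signals = nrow(x),
    max_ror = if (nrow(x) > 0) max(x$ror, na.rm = TRUE) else NA_real_
  )
}

#' Serious case series (one row per qualifying report)
#'
#' Extracts the reports whose seriousness criteria intersect `criteria`
#' (default: death, life-threatening, disability — the case-listing shape
#' used for the most serious reports), one row per case with the
#' display-precedence seriousness label, demographics, suspected and
#' concomitant drugs with indications, reaction PTs, the earliest computable
#' time to onset, outcome, and the causality category when a `causality`
#' column is present on the reports table.
#'
#' @param x An [icsr_set()].
#' @param criteria Seriousness criteria that qualify a report.
#' @param drug_dict Drug dictionary for display names.
#' @return Tibble with one row per qualifying report and attributes
#'   `"age_summary"` and `"tto_summary"` (type-7 median/IQR tibbles from
#'   [quantile_summary()]).
#' @export
case_series <- function(x, criteria = c("death", "life_threatening",
                                        "disability"),
                        drug_dict = ms_drug_dictionary()) {
  stopifnot(inherits(x, "icsr_set"))
  stopifnot(all(criteria %in% pv_seriousness_criteria()))
  rp <- x$reports
  crit_sets <- split_seriousness(rp$seriousness)
  qualifies <- vapply(crit_sets, function(s) any(s %in% criteria), logical(1))
  rp <- rp[qualifies, , drop = FALSE]
  crit_sets <- crit_sets[qualifies]
  if (nrow(rp) == 0L) {
    out <- tibble::tibble(report_id = character(), seriousness = character(),
                          age_years = numeric(), sex = character(),
                          suspected = character(), concomitant = character(),
                          adrs = character(), tto_days = integer(),
                          outcome = character())
    attr(out, "age_summary") <- quantile_summary(numeric(0))
    attr(out, "tto_summary") <- quantile_summary(numeric(0))
    return(out)
  }
  label <- vapply(crit_sets, seriousness_label, character(1))

  dg <- x$drugs[x$drugs$report_id %in% rp$report_id, , drop = FALSE]
  disp_name <- drug_dict$name[match(dg$code, drug_dict$code)]
  disp_name <- ifelse(is.na(disp_name),
                      ifelse(is.na(dg$name), dg$code, dg$name), disp_name)
  dg$label <- ifelse(is.na(dg$indication) | dg$indication == "", disp_name,
                     paste0(disp_name, " (", dg$indication, ")"))
  collapse_by <- function(df) {
    v <- vapply(split(df$label, df$report_id),
                function(s) paste(s, collapse = ", "), character(1))
    v
  }
  sus_lab <- collapse_by(dg[dg$role == "suspected", , drop = FALSE])
  con_lab <- collapse_by(dg[dg$role == "concomitant", , drop = FALSE])

  rx <- x$reactions[x$reactions$report_id %in% rp$report_id, , drop = FALSE]
  term <- ifelse(is.na(rx$pt), rx$verbatim, rx$pt)
  adr_lab <- vapply(split(term, rx$report_id),
                    function(s) paste(sort(unique(s)), collapse = ", "),
                    character(1))

  tt <- compute_tto_ttr(x)
  tt <- tt[tt$report_id %in% rp$report_id & !is.na(tt$tto_days), ,
           drop = FALSE]
  tto_by_report <- vapply(split(tt$tto_days, tt$report_id), min, integer(1))

  out <- tibble::tibble(
    report_id = rp$report_id,
    seriousness = label,
    age_years = rp$age_years,
    sex = rp$sex,
    suspected = unname(sus_lab[rp$report_id]),
    concomitant = unname(con_lab[rp$report_id]),
    adrs = unname(adr_lab[rp$report_id]),
    tto_days = unname(tto_by_report[rp$report_id]),
    outcome = rp$outcome
  )
  if ("causality" %in% names(rp)) out$causality <- rp$causality
  attr(out, "age_summary") <- quantile_summary(out$age_years)
  attr(out, "tto_summary") <- quantile_summary(out$tto_days)
  out
}
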