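#' Default Naranjo item weights
#'
#' The standard ten-item adverse-drug-reaction probability questionnaire:
#' 1. previous conclusive reports on this reaction;
#' 2. event appeared after the suspected drug was given;
#' 3. improvement on dechallenge (drug stopped / antagonist given);
#' 4. reappearance on rechallenge;
#' 5. alternative causes that could have caused the reaction (note the
#'    inverted scoring: "no" scores positive);
#' 6. reaction reappeared on placebo (inverted);
#' 7. drug detected at toxic concentration;
#' 8. dose–response relationship;
#' 9. similar reaction to the same or similar drug in the past;
#' 10. objective confirmation of the event.
#'
#' Scoring is data-driven so questionnaire variants can be swapped in; this
#' table is the canonical instrument (score range -4 to +13).
#'
#' @return Tibble with columns `question` (`q1`..`q10`), `yes`, `no`,
#'   `unknown`.
#' @export
naranjo_weights <- function() {
  tibble::tibble(
    question = paste0("q", 1:10),
    yes = c(1, 2, 1, 2, -1, -1, 1, 1, 1, 1),
    no = c(0, -1, 0, -1, 2, 1, 0, 0, 0, 0),
    unknown = rep(0, 10)
  )
}

#' Score Naranjo questionnaires
#'
#' @param answers Data frame with columns `q1`..`q10`, each one of
#'   `"yes"`, `"no"`, `"unknown"` (one row per drug–event assessment; other
#'   columns such as `report_id` pass through).
#' @param weights Weight table in the shape of [naranjo_weights()].
#' @return The input tibble with an integer `score` column appended.
#' @export
naranjo_score <- function(answers, weights = naranjo_weights()) {
  answers <- tibble::as_tibble(answers)
  qs <- weights$question
  miss <- setdiff(qs, names(answers))
  if (length(miss) > 0L) {
    stop("missing answer column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  score <- rep(0, nrow(answers))
  for (i in seq_along(qs)) {
    a <- answers[[qs[i]]]
    if (anyNA(a) || !all(a %in% c("yes", "no", "unknown"))) {
      stop("answers to ", qs[i], " must be yes/no/unknown with no missing",
           call. = FALSE)
    }
    w <- c(yes = weights$yes[i], no = weights$no[i],
           unknown = weights$unknown[i])
    score <- score + unname(w[a])
  }
  answers$score <- as.integer(score)
  answers
}

#' Map Naranjo scores to causality categories
#'
#' Bands: score >= 9 very likely; 5–8 probable; 1–4 possible; <= 0 doubtful.
#' Bands are total and mutually exclusive over the attainable score range
#' \[-4, 13\]; scores outside that range are rejected as impossible under the
#' standard weights.
#'
#' @param score Integer vector of Naranjo scores.
#' @return Factor with levels `doubtful`, `possible`, `probable`,
#'   `very_likely`.
#' @export
naranjo_classify <- function(score) {
  if (any(is.na(score))) stop("missing score", call. = FALSE)
  if (any(score != round(score))) stop("scores must be integers", call. = FALSE)
  if (any(score < -4 | score > 13)) {
    stop("score outside the attainable range [-4, 13]", call. = FALSE)
  }
  lev <- c("doubtful", "possible", "probable", "very_likely")
  out <- rep("doubtful", length(score))
  out[score >= 1 & score <= 4] <- "possible"
  out[score >= 5 & score <= 8] <- "probable"
  out[score >= 9] <- "very_likely"
  factor(out, levels = lev)
}

#' Time to onset and time to resolution per drug-reaction pair
#'
#' For every (report, suspected drug, reaction) triple: time to onset (TTO)
#' is the days elapsed from the suspected drug's start date to the reaction's
#' onset date; time to resolution (TTR) is the days from onset to resolution.
#' Either is missing whenever a needed date is absent. A negative difference
#' signals a data error (or a misattributed drug): it is reported as a
#' violation flag with a missing TTO/TTR, never as a negative result. TTO is
#' computed per drug–reaction pair, so reports with two suspected drugs used
#' in different periods get one TTO per drug.
#'
#' @param x An [icsr_set()].
#' @return Tibble with columns `report_id`, `code`, `pt`, `verbatim`,
#'   `tto_days`, `ttr_days`, `violation` (`NA` or a short rule name).
#' @export
compute_tto_ttr <- function(x) {
  stopifnot(inherits(x, "icsr_set"))
  sus <- x$drugs[x$drugs$role == "suspected",
                 c("report_id", "code", "start_date")]
  rx <- x$reactions[, c("report_id", "verbatim", "pt", "onset_date",
                        "resolution_date")]
  df <- dplyr::inner_join(sus, rx, by = "report_id",
                          relationship = "many-to-many")
  tto <- as.integer(df$onset_date - df$start_date)
  ttr <- as.integer(df$resolution_date - df$onset_date)
  violation <- rep(NA_character_, nrow(df))
  violation[!is.na(tto) & tto < 0] <- "onset_before_drug_start"
  violation[!is.na(ttr) & ttr < 0] <- "resolution_before_onset"
  tto[!is.na(tto) & tto < 0] <- NA_integer_
  ttr[!is.na(ttr) & ttr < 0] <- NA_integer_
  tibble::tibble(report_id = df$report_id, code = df$code, pt = df$pt,
                 verbatim = df$verbatim, tto_days = tto, ttr_days = ttr,
                 violation = violation)
}

#' Median and IQR of time to onset for one drug
#'
#' @param x An [icsr_set()].
#' @param drug_code Suspected drug code.
#' @param what `"tto_days"` (default) or `"ttr_days"`.
#' @return One-row tibble `n`, `q1`, `median`, `q3` (type-7 quantiles over
#'   the per-reaction values); zero rows when nothing is computable.
#' @export
summarize_tto <- function(x, drug_code, what = c("tto_days", "ttr_days")) {
  what <- match.arg(what)
  tt <- compute_tto_ttr(x)
  quantile_summary(tt[[what]][tt$code == drug_code])
}
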