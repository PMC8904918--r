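#' Configuration for the spontaneous-report generator
#'
#' Defaults emulate the marginal structure of the regional study set this
#' package was designed around: 1,119 reports over 2002–2020, eleven MS
#' drugs with report shares taken from the printed per-drug totals, 3/1,119
#' dual-suspect reports, 72.3% female (1.1% sex missing), age concentrated
#' in the 18–65 band (6.8% missing), per-drug serious-report shares around
#' 26.5% overall, and field-level missingness mirroring the "NA" columns of
#' the descriptive tables. Annual weights default to uniform over the window
#' (no trend shape is assumed). Background reaction rates are per-report
#' Bernoulli probabilities per preferred term; injected signals multiply the
#' event *odds* for reports exposed to the paired drug, so the population
#' reporting odds ratio of an injected pair equals `theta` by construction.
#'
#' @param n_reports Number of reports to simulate.
#' @param seed Integer seed; generation is deterministic given the config.
#' @param window Length-2 Date (or ISO string) vector: receipt-date window.
#' @param drug_shares Named numeric vector (drug code -> share of reports'
#'   primary suspected drug); normalized to sum to 1.
#' @param dual_suspect_prob Probability a report carries a second suspected
#'   drug.
#' @param background_event_rates Named numeric vector (PT -> per-report
#'   probability).
#' @param injected_signals Data frame `drug`, `pt`, `theta` (odds
#'   multiplier > 0) or `NULL`.
#' @param sex_female_prob P(female | sex recorded).
#' @param age_band_weights Length-3 numeric: weights of the `<18`, `18-65`,
#'   `>=66` bands (given age recorded).
#' @param serious_prob Named numeric vector (drug code -> P(serious |
#'   seriousness recorded)); single unnamed value recycled to all drugs.
#' @param serious_criteria_probs Named numeric vector over seriousness
#'   criteria: mix of the qualifying criterion drawn for serious reports.
#' @param outcome_probs Named numeric vector over report outcomes.
#' @param tto_meanlog,tto_sdlog Named numeric vectors (drug code -> log-mean
#'   / log-sd of the lognormal time-to-onset in days); unnamed single values
#'   recycled.
#' @param missingness Named list of per-field missingness probabilities:
#'   `sex`, `age`, `seriousness`, `start_date`, `onset_date`.
#' @param annual_weights Named numeric vector (year -> weight) or `NULL` for
#'   uniform.
#' @param source_probs Named numeric vector over report sources.
#' @param concomitant_prob Probability of one concomitant drug mention.
#' @param duplicate_prob Probability a report is cloned under a new id (a
#'   simple duplicate mechanism for exercising deduplication).
#' @param region Region string stamped on every report.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(
    n_reports = 1119,
    seed = 20021201,
    window = c("2002-01-01", "2020-12-31"),
    drug_shares = c(L03AB07 = 197, L03AB08 = 87, L03AB13 = 38, L03AX13 = 103,
                    L04AA34 = 58, L04AA40 = 31, L04AX07 = 124, L04AA27 = 172,
                    L04AA23 = 212, L04AA36 = 13, L04AA31 = 81),
    dual_suspect_prob = 3 / 1119,
    background_event_rates = c(
      "MS relapse" = 0.102, "Lymphopenia" = 0.094, "Rash" = 0.045,
      "Pyrexia" = 0.043, "Hypertransaminasaemia" = 0.037, "Headache" = 0.034,
      "Pruritus" = 0.026, "Dyslipidaemia" = 0.025, "Nausea" = 0.024,
      "Leukopenia" = 0.024, "Gamma-GT increased" = 0.024,
      "Influenza like illness" = 0.023, "Urticaria" = 0.021,
      "Administration site pain" = 0.021, "Thrombocytopenia" = 0.020,
      "Dyspnoea" = 0.017, "Hypertension" = 0.016, "Herpes zoster" = 0.015,
      "Abortion" = 0.009, "Vitamin D deficiency" = 0.009,
      "Breast cancer" = 0.009, "Hypothyroidism" = 0.004),
    injected_signals = NULL,
    sex_female_prob = 809 / (809 + 298),
    age_band_weights = c(3, 1022, 18),
    serious_prob = c(L03AB07 = 0.181, L03AB08 = 0.314, L03AB13 = 0.206,
                     L03AX13 = 0.263, L04AA34 = 0.268, L04AA40 = 0.161,
                     L04AX07 = 0.264, L04AA27 = 0.353, L04AA23 = 0.333,
                     L04AA36 = 0.538, L04AA31 = 0.288),
    serious_criteria_probs = c(hospitalization = 0.80,
                               other_medically_important = 0.137,
                               life_threatening = 0.037, death = 0.020,
                               disability = 0.006),
    outcome_probs = c(fully_recovered = 0.30, improved = 0.22,
                      not_yet_recovered = 0.18,
                      recovered_with_sequelae = 0.02, death = 0.01,
                      unknown = 0.27),
    tto_meanlog = c(L03AB07 = log(300), L03AB08 = log(1578),
                    L03AB13 = log(300), L03AX13 = log(300),
                    L04AA34 = log(27), L04AA40 = log(220), L04AX07 = log(220),
                    L04AA27 = log(220), L04AA23 = log(220),
                    L04AA36 = log(220), L04AA31 = log(220)),
    tto_sdlog = 1.2,
    missingness = list(sex = 12 / 1119, age = 76 / 1119,
                       seriousness = 76 / 1119, start_date = 0.12,
                       onset_date = 0.08),
    annual_weights = NULL,
    source_probs = c(spontaneous = 0.95, solicited = 0.05, literature = 0),
    concomitant_prob = 0.15,
    duplicate_prob = 0,
    region = "Sicily") {
  window <- as.Date(window)
  stopifnot(length(window) == 2L, window[1] <= window[2], n_reports >= 1)
  drug_shares <- drug_shares / sum(drug_shares)
  if (any(background_event_rates < 0 | background_event_rates > 1) ||
      length(background_event_rates) == 0L ||
      all(background_event_rates == 0)) {
    stop("background_event_rates must contain probabilities, not all zero",
         call. = FALSE)
  }
  if (!is.null(injected_signals)) {
    injected_signals <- tibble::as_tibble(injected_signals)
    stopifnot(all(c("drug", "pt", "theta") %in% names(injected_signals)),
              all(injected_signals$theta > 0),
              all(injected_signals$drug %in% names(drug_shares)),
              all(injected_signals$pt %in% names(background_event_rates)))
  } else {
    injected_signals <- tibble::tibble(drug = character(), pt = character(),
                                       theta = numeric())
  }
  probs01 <- c(dual_suspect_prob, sex_female_prob, concomitant_prob,
               duplicate_prob, unlist(missingness), serious_prob)
  stopifnot(all(probs01 >= 0 & probs01 <= 1))
  structure(list(
    n_reports = as.integer(n_reports), seed = as.integer(seed),
    window = window, drug_shares = drug_shares,
    dual_suspect_prob = dual_suspect_prob,
    background_event_rates = background_event_rates,
    injected_signals = injected_signals,
    sex_female_prob = sex_female_prob, age_band_weights = age_band_weights,
    serious_prob = serious_prob,
    serious_criteria_probs = serious_criteria_probs / sum(serious_criteria_probs),
    outcome_probs = outcome_probs / sum(outcome_probs),
    tto_meanlog = tto_meanlog, tto_sdlog = tto_sdlog,
    missingness = missingness, annual_weights = annual_weights,
    source_probs = source_probs / sum(source_probs),
    concomitant_prob = concomitant_prob, duplicate_prob = duplicate_prob,
    region = region
  ), class = "generator_config")
}

# recycle a possibly-unnamed parameter over drug codes
per_drug <- function(param, codes, default) {
  if (is.null(names(param))) {
    return(stats::setNames(rep(param[1], length(codes)), codes))
  }
  out <- param[codes]
  out[is.na(out)] <- default
  stats::setNames(out, codes)
}

#' Simulate a spontaneous-reporting dataset
#'
#' Draws `cfg$n_reports` individual case safety reports: a receipt date from
#' the annual weights, a primary suspected drug from the drug shares (plus a
#' second suspected drug with the dual-suspect probability), demographics,
#' seriousness and outcome, then a reaction set per report — each preferred
#' term an independent Bernoulli draw whose odds are multiplied by `theta`
#' when the report is exposed to the drug of an injected signal pair. Empty
#' reaction sets are rejection-resampled (every spontaneous report reports at
#' least one reaction); because the resampling conditions identically on the
#' exposed and unexposed arms of any injected pair, the population ROR of an
#' injected pair remains exactly `theta`. Time to onset is drawn lognormal
#' per drug, the drug start date is back-dated so that
#' `onset = start + TTO`, and per-field missingness is applied last.
#'
#' @param cfg A [generator_config()].
#' @param seed Optional integer overriding `cfg$seed`.
#' @return An [icsr_set()] with attribute `"ledger"`: the truth ledger (see
#'   [ledger_audit()]) holding the realized 2x2 cells of every injected pair,
#'   realized stratum counts, and the config's targets.
#' @export
simulate_srs <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(seed %||% cfg$seed)
  n <- cfg$n_reports
  codes <- names(cfg$drug_shares)
  dict <- ms_drug_dictionary()

  # receipt dates
  years <- seq(as.integer(format(cfg$window[1], "%Y")),
               as.integer(format(cfg$window[2], "%Y")))
  w <- if (is.null(cfg$annual_weights)) rep(1, length(years)) else {
    stopifnot(all(as.character(years) %in% names(cfg$annual_weights)))
    cfg$annual_weights[as.character(years)]
  }
  yr <- sample(years, n, replace = TRUE, prob = w)
  receipt <- as.Date(paste0(yr, "-01-01")) +
    sample.int(365, n, replace = TRUE) - 1L
  receipt <- pmin(pmax(receipt, cfg$window[1]), cfg$window[2])

  # suspected drugs
  drug1 <- sample(codes, n, replace = TRUE, prob = cfg$drug_shares)
  dual <- stats::runif(n) < cfg$dual_suspect_prob
  drug2 <- rep(NA_character_, n)
  if (any(dual)) {
    drug2[dual] <- vapply(drug1[dual], function(d) {
      sample(setdiff(codes, d), 1)
    }, character(1))
  }

  # demographics
  sex <- ifelse(stats::runif(n) < cfg$sex_female_prob, "F", "M")
  band <- sample(c("under_18", "adult_18_65", "senior_66_plus"), n,
                 replace = TRUE, prob = cfg$age_band_weights)
  age <- integer(n)
  age[band == "under_18"] <- sample(10:17, sum(band == "under_18"),
                                    replace = TRUE)
  age[band == "adult_18_65"] <- sample(18:65, sum(band == "adult_18_65"),
                                       replace = TRUE)
  age[band == "senior_66_plus"] <- sample(66:85, sum(band == "senior_66_plus"),
                                          replace = TRUE)

  # seriousness and outcome
  p_serious <- per_drug(cfg$serious_prob, codes, mean(cfg$serious_prob))
  serious <- stats::runif(n) < unname(p_serious[drug1])
  criterion <- rep("", n)
  criterion[serious] <- sample(names(cfg$serious_criteria_probs),
                               sum(serious), replace = TRUE,
                               prob = cfg$serious_criteria_probs)
  outcome <- sample(names(cfg$outcome_probs), n, replace = TRUE,
                    prob = cfg$outcome_probs)
  outcome[criterion == "death"] <- "death"
  source <- sample(names(cfg$source_probs), n, replace = TRUE,
                   prob = cfg$source_probs)

  # reaction draws: per-report-per-PT probability, odds boosted on exposure
  pts <- names(cfg$background_event_rates)
  k <- length(pts)
  pmat <- matrix(rep(cfg$background_event_rates, each = n), nrow = n,
                 dimnames = list(NULL, pts))
  if (nrow(cfg$injected_signals) > 0L) {
    for (i in seq_len(nrow(cfg$injected_signals))) {
      s <- cfg$injected_signals[i, ]
      exposed <- drug1 == s$drug | (!is.na(drug2) & drug2 == s$drug)
      p0 <- cfg$background_event_rates[[s$pt]]
      odds <- s$theta * p0 / (1 - p0)
      pmat[exposed, s$pt] <- odds / (1 + odds)
    }
  }
  hit <- matrix(stats::runif(n * k), nrow = n) < pmat
  empty <- which(rowSums(hit) == 0L)
  guard <- 0L
  while (length(empty) > 0L) {
    guard <- guard + 1L
    if (guard > 10000L) stop("reaction resampling did not converge",
                             call. = FALSE)
    redraw <- matrix(stats::runif(length(empty) * k),
                     nrow = length(empty)) < pmat[empty, , drop = FALSE]
    hit[empty, ] <- redraw
    empty <- empty[rowSums(redraw) == 0L]
  }

  # dates: onset shortly before receipt; start back-dated by the drug's TTO
  onset <- receipt - sample.int(60, n, replace = TRUE)
  mlog <- per_drug(cfg$tto_meanlog, codes, mean(cfg$tto_meanlog))
  slog <- per_drug(cfg$tto_sdlog, codes, mean(cfg$tto_sdlog))
  tto1 <- round(stats::rlnorm(n, unname(mlog[drug1]), unname(slog[drug1])))
  start1 <- onset - tto1
  tto2 <- round(stats::rlnorm(n, unname(mlog[drug2] %|na|% 5),
                              unname(slog[drug2] %|na|% 1)))
  start2 <- onset - tto2
  resolved <- outcome %in% c("fully_recovered", "improved")
  ttr <- round(stats::rlnorm(n, log(30), 1))
  resolution <- as.Date(ifelse(resolved, onset + ttr, NA), origin = "1970-01-01")

  report_id <- sprintf("R%06d", seq_len(n))

  # missingness, applied last
  mp <- cfg$missingness
  sex[stats::runif(n) < mp$sex] <- NA
  age_out <- as.numeric(age)
  age_out[stats::runif(n) < mp$age] <- NA
  seriousness <- criterion
  seriousness[stats::runif(n) < mp$seriousness] <- NA
  start1[stats::runif(n) < mp$start_date] <- NA
  onset_out <- onset
  onset_out[stats::runif(n) < mp$onset_date] <- NA

  reports <- tibble::tibble(
    report_id = report_id, region = cfg$region, receipt_date = receipt,
    source = source, sex = sex, age_years = age_out,
    seriousness = seriousness, outcome = outcome,
    comorbidities = NA_character_
  )

  brand1 <- dict$brands[match(drug1, dict$code)]
  brand1 <- vapply(strsplit(brand1, ";", fixed = TRUE), `[`, character(1), 1)
  drugs <- tibble::tibble(
    report_id = report_id, code = drug1,
    name = dict$name[match(drug1, dict$code)], brand = brand1,
    role = "suspected",
    indication = "multiple sclerosis",
    start_date = start1, stop_date = as.Date(NA)
  )
  if (any(dual)) {
    b2 <- dict$brands[match(drug2[dual], dict$code)]
    b2 <- vapply(strsplit(b2, ";", fixed = TRUE), `[`, character(1), 1)
    drugs <- dplyr::bind_rows(drugs, tibble::tibble(
      report_id = report_id[dual], code = drug2[dual],
      name = dict$name[match(drug2[dual], dict$code)], brand = b2,
      role = "suspected", indication = "multiple sclerosis",
      start_date = start2[dual], stop_date = as.Date(NA)
    ))
  }
  conc <- stats::runif(n) < cfg$concomitant_prob
  if (any(conc)) {
    conc_names <- sample(c("paracetamol", "ibuprofen", "vitamin D3",
                           "omeprazole", "levothyroxine"), sum(conc),
                         replace = TRUE)
    drugs <- dplyr::bind_rows(drugs, tibble::tibble(
      report_id = report_id[conc], code = conc_names, name = conc_names,
      brand = NA_character_, role = "concomitant", indication = NA_character_,
      start_date = as.Date(NA), stop_date = as.Date(NA)
    ))
  }

  idx <- which(hit, arr.ind = TRUE)
  reactions <- tibble::tibble(
    report_id = report_id[idx[, 1]],
    verbatim = pts[idx[, 2]],
    onset_date = onset_out[idx[, 1]],
    resolution_date = resolution[idx[, 1]],
    outcome = outcome[idx[, 1]]
  )
  reactions <- reactions[order(reactions$report_id, reactions$verbatim), ]

  # simple duplicate mechanism: clone reports under a new id, later receipt
  if (cfg$duplicate_prob > 0) {
    clone <- which(stats::runif(n) < cfg$duplicate_prob)
    if (length(clone) > 0L) {
      new_id <- sprintf("D%06d", seq_along(clone))
      cl_rp <- reports[clone, ]
      cl_rp$report_id <- new_id
      cl_rp$receipt_date <- cl_rp$receipt_date + 14
      remap <- stats::setNames(new_id, report_id[clone])
      cl_dg <- drugs[drugs$report_id %in% report_id[clone], ]
      cl_dg$report_id <- unname(remap[cl_dg$report_id])
      cl_rx <- reactions[reactions$report_id %in% report_id[clone], ]
      cl_rx$report_id <- unname(remap[cl_rx$report_id])
      reports <- dplyr::bind_rows(reports, cl_rp)
      drugs <- dplyr::bind_rows(drugs, cl_dg)
      reactions <- dplyr::bind_rows(reactions, cl_rx)
    }
  }

  out <- icsr_set(reports, drugs, reactions)
  out <- normalize_reactions(out, default_meddra())
  attr(out, "ledger") <- build_ledger(out, cfg)
  out
}

`%|na|%` <- function(a, b) ifelse(is.na(a), b, a)

# truth ledger: realized quantities, recomputable from the emitted dataset
build_ledger <- function(x, cfg) {
  sig <- cfg$injected_signals
  pair_cells <- if (nrow(sig) > 0L) {
    dplyr::bind_rows(lapply(seq_len(nrow(sig)), function(i) {
      ct <- build_contingency(x, sig$drug[i], sig$pt[i])
      ct$theta <- sig$theta[i]
      ct
    }))
  } else {
    tibble::tibble(drug = character(), pt = character(), a = integer(),
                   b = integer(), c = integer(), d = integer(),
                   n_ref = integer(), theta = numeric())
  }
  rp <- x$reports
  s <- is_serious(rp$seriousness)
  strata <- tibble::tibble(
    stratum = c("n_reports", "female", "male", "sex_missing", "serious",
                "not_serious", "seriousness_missing",
                levels(classify_age_group(1))),
    n = c(nrow(rp), sum(rp$sex == "F", na.rm = TRUE),
          sum(rp$sex == "M", na.rm = TRUE), sum(is.na(rp$sex)),
          sum(s, na.rm = TRUE), sum(!s, na.rm = TRUE), sum(is.na(s)),
          as.integer(table(classify_age_group(rp$age_years))))
  )
  drug_totals <- x$drugs |>
    dplyr::filter(.data$role == "suspected") |>
    dplyr::distinct(.data$report_id, .data$code) |>
    dplyr::count(.data$code, name = "n")
  annual <- rp |>
    dplyr::count(year = as.integer(format(.data$receipt_date, "%Y")),
                 name = "n")
  pt_totals <- x$reactions |>
    dplyr::filter(!is.na(.data$pt)) |>
    dplyr::distinct(.data$report_id, .data$pt) |>
    dplyr::count(.data$pt, name = "n")
  list(pair_cells = pair_cells, strata = strata, drug_totals = drug_totals,
       annual = annual, pt_totals = pt_totals,
       n_drug_rows = nrow(x$drugs), n_reaction_rows = nrow(x$reactions))
}

#' Audit a dataset against its truth ledger
#'
#' Recounts every ledgered quantity from the emitted tables by brute force —
#' per-report logical scans for the 2x2 cells of each injected pair, direct
#' tallies for the stratum, per-drug and annual counts — and compares
#' exactly. Any tampering with the emitted tables (a dropped reaction row, an
#' edited cell) breaks the audit.
#'
#' @param x An [icsr_set()] produced by [simulate_srs()].
#' @param ledger The ledger to audit against; defaults to the one attached
#'   to `x`.
#' @return `TRUE` iff every ledgered quantity matches the recount exactly.
#' @export
ledger_audit <- function(x, ledger = attr(x, "ledger")) {
  stopifnot(inherits(x, "icsr_set"), !is.null(ledger))
  rp <- x$reports
  # literal per-report recount of each ledgered pair
  for (i in seq_len(nrow(ledger$pair_cells))) {
    row <- ledger$pair_cells[i, ]
    a <- b <- c <- d <- 0L
    for (id in rp$report_id) {
      exposed <- any(x$drugs$report_id == id & x$drugs$role == "suspected" &
                       x$drugs$code == row$drug)
      event <- any(x$reactions$report_id == id &
                     !is.na(x$reactions$pt) & x$reactions$pt == row$pt)
      if (exposed && event) a <- a + 1L
      else if (exposed) b <- b + 1L
      else if (event) c <- c + 1L
      else d <- d + 1L
    }
    if (!identical(c(a, b, c, d),
                   as.integer(c(row$a, row$b, row$c, row$d)))) return(FALSE)
  }
  s <- is_serious(rp$seriousness)
  ages <- table(classify_age_group(rp$age_years))
  want <- stats::setNames(ledger$strata$n, ledger$strata$stratum)
  got <- c(n_reports = nrow(rp), female = sum(rp$sex == "F", na.rm = TRUE),
           male = sum(rp$sex == "M", na.rm = TRUE),
           sex_missing = sum(is.na(rp$sex)),
           serious = sum(s, na.rm = TRUE),
           not_serious = sum(!s, na.rm = TRUE),
           seriousness_missing = sum(is.na(s)), as.integer(ages))
  names(got)[8:11] <- names(ages)
  if (!identical(as.integer(want[names(got)]), as.integer(got))) return(FALSE)

  dt <- x$drugs |>
    dplyr::filter(.data$role == "suspected") |>
    dplyr::distinct(.data$report_id, .data$code) |>
    dplyr::count(.data$code, name = "n")
  if (!identical(dplyr::arrange(dt, .data$code),
                 dplyr::arrange(ledger$drug_totals, .data$code))) return(FALSE)
  an <- rp |>
    dplyr::count(year = as.integer(format(.data$receipt_date, "%Y")),
                 name = "n")
  if (!identical(dplyr::arrange(an, .data$year),
                 dplyr::arrange(ledger$annual, .data$year))) return(FALSE)
  pt <- x$reactions |>
    dplyr::filter(!is.na(.data$pt)) |>
    dplyr::distinct(.data$report_id, .data$pt) |>
    dplyr::count(.data$pt, name = "n")
  if (!identical(dplyr::arrange(pt, .data$pt),
                 dplyr::arrange(ledger$pt_totals, .data$pt))) return(FALSE)
  identical(c(ledger$n_drug_rows, ledger$n_reaction_rows),
            c(nrow(x$drugs), nrow(x$reactions)))
}
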