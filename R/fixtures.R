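#' The 19-case serious report series as an ICSR fixture
#'
#' Reconstructs the published regional case listing of reports with
#' life-threatening events, persistent/significant disability or death as a
#' fully-formed [icsr_set()]: ages, sexes, suspected and concomitant drugs
#' with indications, reaction terms, seriousness criteria, outcomes and
#' causality categories as printed. Times to onset are realized by
#' back-dating each study drug's start date from a fixed onset date, so
#' [compute_tto_ttr()] recovers the printed day counts exactly. One case's
#' TTO was printed with a deviant decimal-style thousands separator
#' ("1.214"); it is encoded as 1214 days.
#'
#' @return An [icsr_set()] of 19 reports, with a `causality` column on the
#'   reports table.
#' @export
serious_cases_fixture <- function() {
  tto <- c(58, 196, 991, 299, 853, 1, 240, 1, 184, 184, 900, 410, 139, 1948,
           1214, 654, 898, 2069, 695)
  age <- c(39, 27, 48, 39, 46, 39, 56, 48, 74, 46, 49, 34, 44, 56, 29, 38,
           46, 70, 64)
  sex <- c("F", "M", "M", "F", "F", "M", "F", "F", "M", "F", "M", "M", "F",
           "M", "F", "F", "F", "M", "M")
  seriousness <- c("life_threatening", "life_threatening", "disability",
                   "life_threatening", "life_threatening", "life_threatening",
                   "death", "life_threatening", "death", "life_threatening",
                   "life_threatening", "disability", "life_threatening",
                   "death", "death", "life_threatening", "death",
                   "life_threatening", "death")
  outcome <- c("not_yet_recovered", "unknown", "unknown", "fully_recovered",
               "unknown", "unknown", "death", "improved", "death",
               "fully_recovered", "unknown", "recovered_with_sequelae",
               "unknown", "death", "death", "not_yet_recovered", "death",
               "unknown", "death")
  causality <- c("possible", "probable", "probable", "probable", "probable",
                 "probable", "possible", "possible", "possible", "possible",
                 "possible", "possible", "possible", "possible", "possible",
                 "possible", "probable", "possible", "probable")
  study_drug <- c("L03AB07", "L03AB07", "L03AB07", "L03AX13", "L03AB07",
                  "L03AX13", "L03AB08", "L03AX13", "L04AA23", "L04AA23",
                  "L04AA23", "L03AB07", "L04AA27", "L04AA27", "L04AA34",
                  "L04AA27", "L04AA34", "L04AA23", "L04AA27")
  indication <- c("MS", "MS", "MS", "MS", "RRMS", "MS", "MS", "MS", "RRMS",
                  "MS", "RRMS", "RRMS", "MS", "MS", "MS", "MS", "MS", "MS",
                  "MS")
  id <- sprintf("SC-%02d", 1:19)

  onset <- as.Date("2019-06-01")
  receipt <- onset + 30
  dict <- ms_drug_dictionary()
  reports <- tibble::tibble(
    report_id = id, region = "Sicily", receipt_date = receipt,
    source = "spontaneous", sex = sex, age_years = age,
    seriousness = seriousness, outcome = outcome,
    comorbidities = NA_character_, causality = causality
  )

  drugs <- tibble::tibble(
    report_id = id, code = study_drug,
    name = dict$name[match(study_drug, dict$code)],
    brand = NA_character_, role = "suspected", indication = indication,
    start_date = onset - tto, stop_date = as.Date(NA)
  )
  extra_suspected <- tibble::tribble(
    ~report_id, ~code, ~name, ~indication,
    "SC-12", "paracetamol", "paracetamol", "flu syndrome",
    "SC-12", "tamsulosine", "tamsulosine", "neurogenic bladder",
    "SC-14", "thc_cbd", "delta-9-tetrahydrocannabinol with cannabidiol",
    "muscle spasms"
  ) |>
    dplyr::mutate(brand = NA_character_, role = "suspected",
                  start_date = as.Date(NA), stop_date = as.Date(NA))
  concomitant <- tibble::tribble(
    ~report_id, ~name, ~indication,
    "SC-01", "paracetamol", NA,
    "SC-07", "duloxetine hydrochloride", "major depression",
    "SC-09", "gabapentin", NA,
    "SC-10", "venlafaxine", NA,
    "SC-10", "acetylsalicylic acid", NA,
    "SC-10", "amantadine", NA,
    "SC-10", "baclofen", NA,
    "SC-12", "clonazepam", NA,
    "SC-15", "paracetamol and codeine", "back pain",
    "SC-16", "tolterodine", NA
  ) |>
    dplyr::mutate(code = .data$name, brand = NA_character_,
                  role = "concomitant", start_date = as.Date(NA),
                  stop_date = as.Date(NA))
  drugs <- dplyr::bind_rows(drugs, extra_suspected, concomitant)

  adrs <- list(
    c("Asthenia", "Jaundice", "Urticaria"),
    "Dyspepsia",
    "Hepatic enzyme increased",
    "Anaphylactic reaction",
    "Hepatitis fulminant",
    c("Dyspnoea", "Lip oedema", "Urticaria"),
    "Completed suicide",
    "Rash",
    "Death",
    c("Henoch-Schonlein purpura", "Pruritus", "Tachycardia", "Urticaria"),
    c("Metastases to bone", "Metastases to abdominal wall", "Lung cancer"),
    c("Pyrexia", "Testicular infarction", "Testicular swelling"),
    "Ovarian cancer",
    "Cardiac arrest",
    c("Altered state of consciousness", "Back pain", "Cardiac arrest",
      "Respiratory arrest"),
    "Breast cancer",
    c("Lymphopenia", "Pulmonary oedema", "Pyelonephritis", "Septic shock"),
    c("Aortic aneurysm", "Coronary artery disease", "Aortic valve disease"),
    c("Acute respiratory distress syndrome", "COVID-19")
  )
  reactions <- tibble::tibble(
    report_id = rep(id, lengths(adrs)),
    verbatim = unlist(adrs),
    onset_date = onset,
    resolution_date = as.Date(NA),
    outcome = rep(outcome, lengths(adrs))
  )

  normalize_reactions(icsr_set(reports, drugs, reactions), default_meddra())
}

# read one of the bundled aggregated stratified tables
read_strat_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pvsignal", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    drug = readr::col_character(), .default = readr::col_integer()),
    progress = FALSE)
}

#' National aggregated stratified counts (2002-2020)
#'
#' The published national per-drug totals stratified by seriousness, sex and
#' age band — aggregated open data, shipped as a plain-CSV study input. Blank
#' printed cells are zeros. One row per drug plus the `Total` row.
#'
#' @return Tibble with columns `drug`, `total`, `serious`, `not_serious`,
#'   `seriousness_na`, `female`, `male`, `sex_na`, `age_under_18`,
#'   `age_18_65`, `age_66_plus`, `age_na`.
#' @export
national_strat_table <- function() read_strat_extdata("ram_national_table.csv")

#' Regional (Sicilian) aggregated stratified counts (2002-2020)
#'
#' Same layout as [national_strat_table()] for the regional study set,
#' including the dual-suspect combined row. These marginals are what the
#' default [generator_config()] emulates.
#'
#' @return Tibble in the layout of [national_strat_table()].
#' @export
regional_strat_table <- function() read_strat_extdata("rnf_regional_table.csv")
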