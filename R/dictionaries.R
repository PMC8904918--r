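#' MedDRA-like reaction dictionary
#'
#' A minimal two-level terminology: a preferred-term (PT) to system-organ-class
#' (SOC) map plus optional synonym groups that fold alias terms of the same
#' clinical condition into a single canonical PT. Aliasing is single-hop: an
#' alias maps directly to a canonical PT, and canonical targets may not
#' themselves be aliases.
#'
#' @param pt_to_soc Data frame with columns `pt`, `soc`; one row per PT, each
#'   PT mapped to exactly one SOC.
#' @param synonym_groups Data frame with columns `alias`, `pt` (the canonical
#'   target), or `NULL` for no synonym folding.
#' @return An object of class `meddra_dictionary`.
#' @export
meddra_dictionary <- function(pt_to_soc, synonym_groups = NULL) {
  pt_to_soc <- tibble::as_tibble(pt_to_soc)
  stopifnot(all(c("pt", "soc") %in% names(pt_to_soc)))
  if (anyDuplicated(pt_to_soc$pt)) {
    dup <- unique(pt_to_soc$pt[duplicated(pt_to_soc$pt)])
    stop("PT mapped to more than one SOC: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(synonym_groups)) {
    synonym_groups <- tibble::tibble(alias = character(), pt = character())
  }
  synonym_groups <- tibble::as_tibble(synonym_groups)
  stopifnot(all(c("alias", "pt") %in% names(synonym_groups)))
  missing_target <- setdiff(synonym_groups$pt, pt_to_soc$pt)
  if (length(missing_target) > 0L) {
    stop("synonym targets not in pt_to_soc: ",
         paste(missing_target, collapse = ", "), call. = FALSE)
  }
  chained <- intersect(synonym_groups$pt, synonym_groups$alias)
  if (length(chained) > 0L) {
    stop("synonym aliasing must be single-hop; these targets are also ",
         "aliases: ", paste(chained, collapse = ", "), call. = FALSE)
  }
  structure(list(pt_to_soc = pt_to_soc, synonym_groups = synonym_groups),
            class = "meddra_dictionary")
}

#' @export
print.meddra_dictionary <- function(x, ...) {
  cat("<meddra_dictionary> ", nrow(x$pt_to_soc), " PTs, ",
      length(unique(x$pt_to_soc$soc)), " SOCs, ",
      nrow(x$synonym_groups), " synonym aliases\n", sep = "")
  invisible(x)
}

#' Resolve verbatim terms to canonical PTs
#'
#' Applies single-hop synonym folding; terms that are already canonical PTs
#' (or unknown) pass through unchanged.
#'
#' @param terms Character vector of verbatim or PT terms.
#' @param dict A [meddra_dictionary()].
#' @return Character vector of canonical terms, same length as `terms`.
#' @export
canonical_pt <- function(terms, dict) {
  stopifnot(inherits(dict, "meddra_dictionary"))
  i <- match(terms, dict$synonym_groups$alias)
  out <- as.character(terms)
  out[!is.na(i)] <- dict$synonym_groups$pt[i[!is.na(i)]]
  out
}

#' Look up the SOC of canonical PTs
#'
#' @param pts Character vector of canonical PTs.
#' @param dict A [meddra_dictionary()].
#' @return Character vector of SOCs; `NA` where the PT is not in the
#'   dictionary.
#' @export
pt_soc <- function(pts, dict) {
  stopifnot(inherits(dict, "meddra_dictionary"))
  dict$pt_to_soc$soc[match(pts, dict$pt_to_soc$pt)]
}

#' SmPC expectedness registry
#'
#' Maps each study drug to the set of preferred terms listed in its Summary of
#' Product Characteristics (its label). Events absent from a drug's set are
#' "unexpected" and eligible for disproportionality screening.
#'
#' @param expected Named list: drug code -> character vector of expected PTs.
#' @param drug_codes Optional character vector of the study drug list; when
#'   given, every registry key must belong to it.
#' @return An object of class `smpc_registry`.
#' @export
smpc_registry <- function(expected, drug_codes = NULL) {
  stopifnot(is.list(expected), !is.null(names(expected)))
  if (!is.null(drug_codes)) {
    extra <- setdiff(names(expected), drug_codes)
    if (length(extra) > 0L) {
      stop("registry keys not in the study drug list: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  expected <- lapply(expected, as.character)
  structure(list(expected = expected), class = "smpc_registry")
}

#' @export
print.smpc_registry <- function(x, ...) {
  cat("<smpc_registry> ", length(x$expected), " drugs, ",
      sum(lengths(x$expected)), " expected PT entries\n", sep = "")
  invisible(x)
}

#' Study drug dictionary for multiple-sclerosis disease-modifying therapies
#'
#' The eleven MS drugs under surveillance, keyed by ATC code, with common
#' abbreviation, brand names, and immunological class (the four injectable
#' first-line products are immunostimulants, the rest immunosuppressants).
#' Cladribine carries a brand restriction in the default study config: only
#' the MS-indicated brand (Mavenclad) is in scope.
#'
#' @return Tibble with columns `code`, `name`, `abbrev`, `brands`
#'   (semicolon-joined), `class`.
#' @export
ms_drug_dictionary <- function() {
  tibble::tribble(
    ~code,     ~name,                  ~abbrev,        ~brands,            ~class,
    "L03AB07", "interferon beta-1a",   "IFN beta-1a",  "Avonex;Rebif",     "immunostimulant",
    "L03AB08", "interferon beta-1b",   "IFN beta-1b",  "Betaferon",        "immunostimulant",
    "L03AB13", "peginterferon beta-1a","PEG-IFN beta-1a","Plegridy",       "immunostimulant",
    "L03AX13", "glatiramer acetate",   "GA",           "Copaxone",         "immunostimulant",
    "L04AA23", "natalizumab",          "NTZ",          "Tysabri",          "immunosuppressant",
    "L04AA27", "fingolimod",           "FNG",          "Gilenya",          "immunosuppressant",
    "L04AA31", "teriflunomide",        "TRF",          "Aubagio",          "immunosuppressant",
    "L04AX07", "dimethyl fumarate",    "DMF",          "Tecfidera",        "immunosuppressant",
    "L04AA34", "alemtuzumab",          "Alem",         "Lemtrada",         "immunosuppressant",
    "L04AA36", "ocrelizumab",          "OCZ",          "Ocrevus",          "immunosuppressant",
    "L04AA40", "cladribine",           "Cladr",        "Mavenclad",        "immunosuppressant"
  )
}

#' Built-in demonstration PT -> SOC dictionary
#'
#' A small MedDRA-style map covering the preferred terms used by the synthetic
#' generator and the bundled case fixtures. It is an illustrative synthetic
#' terminology, not licensed MedDRA content; real analyses should load their
#' own dictionary with [read_meddra_yaml()]. Ships with an empty synonym map:
#' which PT synonyms to merge is study-specific user configuration.
#'
#' @return A [meddra_dictionary()].
#' @export
default_meddra <- function() {
  soc <- list(
    "General disorders and administration site conditions" = c(
      "Pyrexia", "Asthenia", "Administration site pain",
      "Influenza like illness", "Death"),
    "Nervous system disorders" = c(
      "Headache", "MS relapse", "Dizziness", "Paresthesia",
      "Altered state of consciousness"),
    "Skin and subcutaneous tissue disorders" = c(
      "Rash", "Pruritus", "Urticaria", "Alopecia"),
    "Blood and lymphatic system disorders" = c(
      "Lymphopenia", "Leukopenia", "Thrombocytopenia"),
    "Investigations" = c(
      "Gamma-GT increased", "ALT increased", "ASP increased",
      "Hepatic enzyme increased", "JC polyomavirus test positive"),
    "Infections and infestations" = c(
      "Herpes zoster", "Influenza", "Urinary tract infection",
      "Progressive multifocal leukoencephalopathy", "Viral infection",
      "COVID-19", "Pyelonephritis", "Septic shock"),
    "Gastrointestinal disorders" = c(
      "Abdominal pain", "Nausea", "Diarrhoea", "Vomiting", "Dyspepsia",
      "Lip oedema"),
    "Cardiac disorders" = c(
      "Bradycardia", "Tachycardia", "Palpitations", "Cardiac arrest",
      "Extrasystoles", "Coronary artery disease", "Aortic valve disease"),
    "Respiratory, thoracic and mediastinal disorders" = c(
      "Dyspnoea", "Cough", "Pneumonitis", "Respiratory arrest",
      "Acute respiratory distress syndrome", "Pulmonary oedema", "Choking"),
    "Musculoskeletal and connective tissue disorders" = c(
      "Myalgia", "Arthralgia", "Pain in extremity", "Back pain",
      "Muscle spasms"),
    "Vascular disorders" = c(
      "Flushing", "Hypertension", "Hot flushes", "Aortic aneurysm",
      "Henoch-Schonlein purpura"),
    "Neoplasms benign, malignant and unspecified" = c(
      "Breast cancer", "Malignant melanoma", "Basal cell carcinoma",
      "Lung cancer", "Ovarian cancer", "Prostate cancer",
      "Metastases to bone", "Metastases to abdominal wall", "Naevus"),
    "Psychiatric disorders" = c(
      "Insomnia", "Depression", "Anxiety", "Completed suicide"),
    "Hepatobiliary disorders" = c(
      "Hypertransaminasaemia", "Hyperbilirubinaemia", "Liver injury",
      "Jaundice", "Hepatitis fulminant"),
    "Metabolism and nutrition disorders" = c(
      "Dyslipidaemia", "Decreased appetite", "Vitamin D deficiency"),
    "Eye disorders" = c("Vision blurred", "Visual impairment", "Eye oedema"),
    "Pregnancy, puerperium and perinatal conditions" = c("Abortion"),
    "Reproductive system and breast disorders" = c(
      "Amenorrhoea", "Testicular infarction", "Testicular swelling",
      "Breast mass"),
    "Renal and urinary disorders" = c("Proteinuria", "Renal colic"),
    "Immune system disorders" = c(
      "Hypersensitivity", "Anaphylactic shock", "Anaphylactic reaction"),
    "Endocrine disorders" = c(
      "Autoimmune thyroiditis", "Hypothyroidism", "Hyperthyroidism",
      "Thyroiditis"),
    "Injury, poisoning and procedural complications" = c(
      "Administration related reaction", "Maternal exposure during pregnancy",
      "Skin wound")
  )
  pt_to_soc <- tibble::tibble(
    pt = unlist(soc, use.names = FALSE),
    soc = rep(names(soc), lengths(soc))
  )
  meddra_dictionary(pt_to_soc)
}

#' Built-in demonstration SmPC expectedness registry
#'
#' A synthetic illustrative registry marking, for each study drug, a set of
#' label-listed (expected) preferred terms consistent with the drugs'
#' well-known safety profiles: injection-site and flu-like reactions for the
#' injectable immunostimulants, lymphopenia and liver enzyme changes for the
#' oral immunosuppressants, bradycardia for fingolimod, PML for natalizumab,
#' and so on. Real screening must use a registry transcribed from the current
#' SmPCs ([read_smpc_yaml()]); this default exists so the screening stage is
#' runnable end-to-end on synthetic data.
#'
#' @return An [smpc_registry()].
#' @export
default_smpc <- function() {
  injectable <- c("Administration site pain", "Influenza like illness",
                  "Pyrexia", "Asthenia", "Headache", "Myalgia", "Rash",
                  "MS relapse", "Urticaria", "Hypersensitivity")
  liver <- c("Hypertransaminasaemia", "ALT increased", "Gamma-GT increased",
             "Hepatic enzyme increased")
  expected <- list(
    L03AB07 = c(injectable, "Depression", liver),
    L03AB08 = c(injectable, "Depression", liver, "Completed suicide"),
    L03AB13 = c(injectable, liver),
    L03AX13 = c(injectable, "Dyspnoea", "Anaphylactic reaction",
                "Hot flushes", "Tachycardia"),
    L04AA23 = c("Progressive multifocal leukoencephalopathy", "Headache",
                "Urinary tract infection", "Hypersensitivity", "Urticaria",
                "MS relapse", "JC polyomavirus test positive", "Pruritus",
                "Nausea", liver),
    L04AA27 = c("Lymphopenia", "Leukopenia", "Bradycardia", "Headache",
                "Basal cell carcinoma", "Herpes zoster", "Hypertension",
                "MS relapse", "Vision blurred", liver),
    L04AA31 = c("Diarrhoea", "Nausea", "Alopecia", "Hypertension",
                "Headache", liver),
    L04AX07 = c("Flushing", "Diarrhoea", "Nausea", "Abdominal pain",
                "Lymphopenia", "Leukopenia", "Rash", "Pruritus", liver),
    L04AA34 = c("Rash", "Headache", "Pyrexia", "Thyroiditis",
                "Autoimmune thyroiditis", "Hyperthyroidism", "Hypothyroidism",
                "Lymphopenia", "Urticaria", "Pruritus", "Insomnia", "Nausea"),
    L04AA36 = c("Viral infection", "Herpes zoster", "Cough", "Dyspnoea",
                "Urinary tract infection", "Hypersensitivity"),
    L04AA40 = c("Lymphopenia", "Herpes zoster", "Rash", "Alopecia",
                "Headache")
  )
  smpc_registry(expected, drug_codes = ms_drug_dictionary()$code)
}

#' Read a reaction dictionary from YAML
#'
#' Expected layout: top-level keys `pt_to_soc` (map PT -> SOC) and optional
#' `synonym_groups` (map alias -> canonical PT).
#'
#' @param path Path to a YAML file.
#' @return A [meddra_dictionary()].
#' @export
read_meddra_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$pt_to_soc)) stop("missing `pt_to_soc` key", call. = FALSE)
  pt_to_soc <- tibble::tibble(pt = names(y$pt_to_soc),
                              soc = unlist(y$pt_to_soc, use.names = FALSE))
  syn <- NULL
  if (!is.null(y$synonym_groups) && length(y$synonym_groups) > 0) {
    syn <- tibble::tibble(alias = names(y$synonym_groups),
                          pt = unlist(y$synonym_groups, use.names = FALSE))
  }
  meddra_dictionary(pt_to_soc, syn)
}

#' Read an SmPC expectedness registry from YAML
#'
#' Expected layout: top-level key `expected` mapping drug code to a list of
#' expected PTs.
#'
#' @param path Path to a YAML file.
#' @param drug_codes Optional study drug list for key validation.
#' @return An [smpc_registry()].
#' @export
read_smpc_yaml <- function(path, drug_codes = NULL) {
  y <- yaml::read_yaml(path)
  if (is.null(y$expected)) stop("missing `expected` key", call. = FALSE)
  smpc_registry(y$expected, drug_codes = drug_codes)
}
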