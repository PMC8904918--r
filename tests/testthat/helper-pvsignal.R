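# Builders for small hand-made ICSR sets, and independent oracles used to
# cross-check the package's counting and quantile paths.

mk_reports <- function(ids, receipt = "2019-06-01", source = "spontaneous",
                       sex = "F", age = 40, seriousness = "",
                       outcome = "unknown", region = "Sicily") {
  tibble::tibble(
    report_id = ids, region = region,
    receipt_date = as.Date(rep_len(receipt, length(ids))),
    source = rep_len(source, length(ids)),
    sex = rep_len(sex, length(ids)),
    age_years = rep_len(age, length(ids)),
    seriousness = rep_len(seriousness, length(ids)),
    outcome = rep_len(outcome, length(ids)),
    comorbidities = NA_character_
  )
}

mk_drug <- function(id, code, role = "suspected", brand = NA_character_,
                    start = NA, stop = NA, name = code, indication = NA) {
  tibble::tibble(report_id = id, code = code, name = name, brand = brand,
                 role = role, indication = as.character(indication),
                 start_date = as.Date(start), stop_date = as.Date(stop))
}

mk_reaction <- function(id, verbatim, onset = NA, resolution = NA) {
  tibble::tibble(report_id = id, verbatim = verbatim,
                 onset_date = as.Date(onset),
                 resolution_date = as.Date(resolution),
                 outcome = NA_character_)
}

# a minimal valid set: each report one suspected drug and one reaction
mk_simple_set <- function(ids, codes, pts, ...) {
  icsr_set(
    mk_reports(ids, ...),
    dplyr::bind_rows(purrr::map2(ids, rep_len(codes, length(ids)), mk_drug)),
    dplyr::bind_rows(purrr::map2(ids, rep_len(pts, length(ids)), mk_reaction))
  )
}

# literal-definition 2x2 recount: one pass over reports, no joins
oracle_contingency <- function(x, drug_code, pt) {
  a <- b <- cc <- d <- 0L
  for (id in x$reports$report_id) {
    exposed <- any(x$drugs$report_id == id & x$drugs$role == "suspected" &
                     x$drugs$code == drug_code)
    event <- any(x$reactions$report_id == id & !is.na(x$reactions$pt) &
                   x$reactions$pt == pt)
    if (exposed && event) a <- a + 1L
    else if (exposed) b <- b + 1L
    else if (event) cc <- cc + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

# sort-and-interpolate quantile oracle (rank h = (n-1)p + 1)
oracle_quantile7 <- function(values, p) {
  v <- sort(values)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# random tiny ICSR set for property tests
random_small_set <- function(n, n_drugs = 3, n_pts = 3) {
  codes <- paste0("D", seq_len(n_drugs))
  pts <- paste0("PT", seq_len(n_pts))
  ids <- sprintf("r%03d", seq_len(n))
  drugs <- dplyr::bind_rows(lapply(ids, function(id) {
    k <- sample(1:2, 1)
    mk_drug(rep(id, k), sample(codes, k))
  }))
  rx <- dplyr::bind_rows(lapply(ids, function(id) {
    k <- sample(1:3, 1)
    mk_reaction(rep(id, k), sample(pts, k, replace = TRUE))
  }))
  x <- icsr_set(mk_reports(ids), drugs, rx)
  x$reactions$pt <- x$reactions$verbatim
  x$reactions$soc <- "Synthetic"
  x
}
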