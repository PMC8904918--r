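write_trio <- function(x, dir) {
  write_icsr(x, dir)
  file.path(dir, c("reports.csv", "drugs.csv", "reactions.csv"))
}

test_that("a small CSV trio loads with reconciled counts", {
  dir <- withr::local_tempdir()
  x <- icsr_set(
    mk_reports(c("r1", "r2", "r3")),
    dplyr::bind_rows(
      mk_drug(c("r1", "r1"), c("D1", "paracetamol"),
              role = c("suspected", "concomitant")),
      mk_drug(c("r2", "r2"), c("D2", "D1")),
      mk_drug("r3", "D1")
    ),
    mk_reaction(c("r1", "r2", "r2", "r3"),
                c("Pyrexia", "Rash", "Nausea", "Headache"))
  )
  p <- write_trio(x, dir)
  got <- read_icsr(p[1], p[2], p[3])
  log <- attr(got, "log")
  expect_equal(log$n_reports, 3L)
  expect_equal(log$n_drug_rows, 5L)
  expect_equal(log$n_reaction_rows, 4L)
  expect_equal(log$n_orphans, 0L)
})

test_that("orphan rows abort the load unless explicitly allowed", {
  dir <- withr::local_tempdir()
  x <- mk_simple_set(c("r1", "r2"), "D1", "Pyrexia")
  p <- write_trio(x, dir)
  rx <- readr::read_csv(p[3], show_col_types = FALSE)
  rx <- dplyr::bind_rows(rx, dplyr::mutate(rx[1, ], report_id = "ghost"))
  readr::write_csv(rx, p[3])
  expect_error(read_icsr(p[1], p[2], p[3]), "ghost")
  got <- read_icsr(p[1], p[2], p[3], allow_orphans = TRUE)
  expect_equal(attr(got, "log")$n_orphans, 1L)
  expect_equal(nrow(got$reactions), 2L)
})

test_that("non-ISO dates are a parse error, not a silent NA", {
  dir <- withr::local_tempdir()
  x <- mk_simple_set("r1", "D1", "Pyrexia")
  p <- write_trio(x, dir)
  rp <- readr::read_csv(p[1], show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  rp$receipt_date <- "06/01/2019"
  readr::write_csv(rp, p[1])
  expect_error(read_icsr(p[1], p[2], p[3]), "ISO-8601")
})

test_that("a simulated dataset round-trips write -> load with field equality", {
  dir <- withr::local_tempdir()
  x <- simulate_srs(generator_config(n_reports = 300, seed = 42))
  p <- write_trio(x, dir)
  got <- read_icsr(p[1], p[2], p[3])
  for (col in c("report_id", "receipt_date", "source", "sex", "age_years",
                "seriousness", "outcome")) {
    expect_equal(got$reports[[col]], x$reports[[col]], info = col)
  }
  expect_equal(got$drugs[order(got$drugs$report_id, got$drugs$code), ]$code,
               x$drugs[order(x$drugs$report_id, x$drugs$code), ]$code)
  expect_equal(nrow(got$reactions), nrow(x$reactions))
  expect_equal(got$reactions$onset_date, x$reactions$onset_date)
})

test_that("inclusion rules exclude with the documented single reasons", {
  cfg <- ms_study_config()
  x <- icsr_set(
    mk_reports(c("ok", "early", "lit", "wrongbrand", "otherdrug"),
               receipt = c("2019-06-01", "2001-12-30", "2019-06-01",
                           "2019-06-01", "2019-06-01"),
               source = c("spontaneous", "spontaneous", "literature",
                          "spontaneous", "spontaneous")),
    dplyr::bind_rows(
      mk_drug("ok", "L04AA27"),
      mk_drug("early", "L04AA27"),
      mk_drug("lit", "L04AA27"),
      mk_drug("wrongbrand", "L04AA40", brand = "Litak"),
      mk_drug("otherdrug", "aspirin")
    ),
    mk_reaction(c("ok", "early", "lit", "wrongbrand", "otherdrug"), "Pyrexia")
  )
  res <- apply_inclusion(x, cfg)
  expect_equal(res$kept$reports$report_id, "ok")
  reasons <- setNames(res$excluded$reason, res$excluded$report_id)
  expect_equal(reasons[["early"]], "out_of_window")
  expect_equal(reasons[["lit"]], "source_excluded")
  expect_equal(reasons[["wrongbrand"]], "brand_restriction")
  expect_equal(reasons[["otherdrug"]], "no_qualifying_suspected_drug")
  # conservation
  expect_equal(n_reports(res$kept) + nrow(res$excluded), n_reports(x))
})

test_that("the restricted drug is kept under the required brand", {
  cfg <- ms_study_config()
  x <- icsr_set(
    mk_reports("m1"),
    mk_drug("m1", "L04AA40", brand = "Mavenclad"),
    mk_reaction("m1", "Lymphopenia")
  )
  expect_equal(apply_inclusion(x, cfg)$kept$reports$report_id, "m1")
})

test_that("exclusion reason precedence is window before source", {
  cfg <- ms_study_config()
  x <- icsr_set(
    mk_reports("r1", receipt = "2021-05-01", source = "literature"),
    mk_drug("r1", "L04AA27"),
    mk_reaction("r1", "Pyrexia")
  )
  expect_equal(apply_inclusion(x, cfg)$excluded$reason, "out_of_window")
})

test_that("inclusion and dedup are order-insensitive and non-mutating", {
  x <- simulate_srs(generator_config(n_reports = 120, seed = 9,
                                     duplicate_prob = 0.1,
                                     source_probs = c(spontaneous = 0.8,
                                                      solicited = 0.1,
                                                      literature = 0.1)))
  snapshot <- x$reports
  cfg <- ms_study_config()
  perm <- withr::with_seed(1, sample(nrow(x$reports)))
  xp <- icsr_set(x$reports[perm, ], x$drugs, x$reactions)
  expect_setequal(apply_inclusion(x, cfg)$kept$reports$report_id,
                  apply_inclusion(xp, cfg)$kept$reports$report_id)
  expect_setequal(deduplicate_reports(x)$unique$reports$report_id,
                  deduplicate_reports(xp)$unique$reports$report_id)
  expect_identical(x$reports, snapshot)
})

test_that("deduplication keeps the earliest receipt, ties by report_id", {
  base <- function(id, receipt) icsr_set(
    mk_reports(id, receipt = receipt, sex = "F", age = 44),
    mk_drug(id, "L04AA27"),
    mk_reaction(id, "Rash", onset = "2019-01-01")
  )
  x <- icsr_set(
    dplyr::bind_rows(base("b", "2019-02-01")$reports,
                     base("a", "2019-01-05")$reports),
    dplyr::bind_rows(mk_drug("b", "L04AA27"), mk_drug("a", "L04AA27")),
    dplyr::bind_rows(mk_reaction("b", "Rash", onset = "2019-01-01"),
                     mk_reaction("a", "Rash", onset = "2019-01-01"))
  )
  res <- deduplicate_reports(x)
  expect_equal(res$unique$reports$report_id, "a")
  expect_equal(res$duplicates$report_id, "b")
  expect_equal(res$duplicates$kept_id, "a")

  # tie on receipt date: lexicographically first id wins
  x$reports$receipt_date <- as.Date("2019-01-05")
  expect_equal(deduplicate_reports(x)$unique$reports$report_id, "a")
})

test_that("three-way duplicate groups keep exactly one report", {
  ids <- c("x1", "x2", "x3", "y1")
  x <- icsr_set(
    mk_reports(ids, receipt = c("2019-03-01", "2019-01-01", "2019-02-01",
                                "2019-01-01"),
               age = c(50, 50, 50, 23)),
    dplyr::bind_rows(lapply(ids, mk_drug, code = "L04AA23")),
    dplyr::bind_rows(lapply(ids, mk_reaction, verbatim = "Headache"))
  )
  res <- deduplicate_reports(x)
  expect_setequal(res$unique$reports$report_id, c("x2", "y1"))
  expect_equal(sort(res$duplicates$report_id), c("x1", "x3"))
  # accounting: |unique| + sum(group sizes - 1) = |input|
  expect_equal(n_reports(res$unique) + nrow(res$duplicates), n_reports(x))
})

test_that("deduplication is idempotent and identity on distinct input", {
  x <- simulate_srs(generator_config(n_reports = 150, seed = 5,
                                     duplicate_prob = 0.15))
  once <- deduplicate_reports(x)
  expect_gt(nrow(once$duplicates), 0)
  twice <- deduplicate_reports(once$unique)
  expect_equal(nrow(twice$duplicates), 0L)
  expect_identical(sort(twice$unique$reports$report_id),
                   sort(once$unique$reports$report_id))
})
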