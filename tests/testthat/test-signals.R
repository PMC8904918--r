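test_that("expectedness lookup is registry-driven with forced coverage", {
  reg <- smpc_registry(list(L04AA27 = c("Lymphopenia", "Bradycardia"),
                            L04AA23 = character(0)))
  expect_true(is_expected("L04AA27", "Lymphopenia", reg))
  expect_false(is_expected("L04AA23", "Dyslipidaemia", reg))
  expect_false(is_expected("L04AA23", "Lymphopenia", reg))  # empty set
  expect_error(is_expected("L04AA31", "Rash", reg), "absent from")
  # synonym canonicalization happens before lookup
  dict <- meddra_dictionary(
    tibble::tibble(pt = "Lymphopenia",
                   soc = "Blood and lymphatic system disorders"),
    tibble::tibble(alias = "Lymphocyte count decreased", pt = "Lymphopenia"))
  expect_true(is_expected("L04AA27", "Lymphocyte count decreased", reg, dict))
})

test_that("the 2x2 partitions an exhaustive four-report reference set", {
  x <- icsr_set(
    mk_reports(c("de", "d", "e", "n")),
    dplyr::bind_rows(mk_drug("de", "D"), mk_drug("d", "D"),
                     mk_drug("e", "Z"), mk_drug("n", "Z")),
    dplyr::bind_rows(mk_reaction("de", "E"), mk_reaction("d", "F"),
                     mk_reaction("e", "E"), mk_reaction("n", "F"))
  )
  x$reactions$pt <- x$reactions$verbatim
  ct <- build_contingency(x, "D", "E")
  expect_equal(c(ct$a, ct$b, ct$c, ct$d), c(1L, 1L, 1L, 1L))
  expect_equal(ct$n_ref, 4L)
  expect_error(build_contingency(
    icsr_set(mk_reports(character(0)), mk_drug(character(0), character(0)),
             mk_reaction(character(0), character(0))), "D", "E"),
    "empty reference")
})

test_that("dual-suspect reports contribute to both drugs' exposed cells", {
  x <- icsr_set(
    mk_reports(c("dual", "other")),
    dplyr::bind_rows(mk_drug(c("dual", "dual"), c("D1", "D2")),
                     mk_drug("other", "D3")),
    dplyr::bind_rows(mk_reaction("dual", "E"), mk_reaction("other", "F"))
  )
  x$reactions$pt <- x$reactions$verbatim
  expect_equal(build_contingency(x, "D1", "E")$a, 1L)
  expect_equal(build_contingency(x, "D2", "E")$a, 1L)
  # margin conservation: D1's exposed margin a+b equals its report count
  ct <- build_contingency(x, "D1", "E")
  expect_equal(ct$a + ct$b, 1L)
  expect_equal(ct$a + ct$b + ct$c + ct$d, 2L)
})

test_that("contingency cells agree with the literal recount on random sets", {
  withr::with_seed(123, {
    for (i in 1:50) {
      x <- random_small_set(sample(3:12, 1))
      drug <- sample(unique(x$drugs$code), 1)
      pt <- sample(unique(x$reactions$pt), 1)
      ct <- build_contingency(x, drug, pt)
      expect_equal(c(a = ct$a, b = ct$b, c = ct$c, d = ct$d),
                   oracle_contingency(x, drug, pt))
      expect_equal(ct$a + ct$b + ct$c + ct$d, n_reports(x))
    }
  })
})

test_that("ROR and Woolf CI evaluate the closed forms", {
  r <- ror_woolf(tibble::tibble(a = 10, b = 10, c = 10, d = 10))
  expect_equal(r$ror, 1)
  expect_equal(log(r$ci_low), -log(r$ci_high))  # symmetric on log scale

  # direct evaluation, independently recomputed here
  r2 <- ror_woolf(tibble::tibble(a = 9, b = 91, c = 2, d = 1898))
  expect_equal(r2$ror, 9 * 1898 / (91 * 2), tolerance = 1e-12)
  se <- sqrt(1 / 9 + 1 / 91 + 1 / 2 + 1 / 1898)
  expect_equal(r2$ci_low, exp(log(r2$ror) - 1.96 * se), tolerance = 1e-12)
  expect_equal(r2$ci_high, exp(log(r2$ror) + 1.96 * se), tolerance = 1e-12)
  expect_true(r2$eligible)
})

test_that("zero cells yield indeterminate estimates unless corrected", {
  z <- ror_woolf(tibble::tibble(a = 5, b = 10, c = 0, d = 100))
  expect_true(z$indeterminate)
  expect_true(is.na(z$ror) && is.na(z$ci_low) && is.na(z$ci_high))
  h <- ror_woolf(tibble::tibble(a = 5, b = 10, c = 0, d = 100),
                 haldane = TRUE)
  expect_false(h$indeterminate)
  expect_equal(h$ror, (5.5 * 100.5) / (10.5 * 0.5), tolerance = 1e-12)
  expect_error(ror_woolf(tibble::tibble(a = -1, b = 1, c = 1, d = 1)),
               "negative")
})

test_that("ROR is strictly increasing in the a-cell", {
  rors <- ror_woolf(tibble::tibble(a = 1:20, b = 50, c = 30, d = 500))$ror
  expect_true(all(diff(rors) > 0))
})

test_that("the Woolf CI is log-symmetric: geometric mean recovers the ROR", {
  expect_equal(ror_from_ci(7, 7), 7)
  expect_error(ror_from_ci(-1, 2), "positive")
  expect_error(ror_from_ci(3, 2), "ci_low")
  withr::with_seed(5, {
    tabs <- tibble::tibble(a = sample(1:50, 100, TRUE),
                           b = sample(1:500, 100, TRUE),
                           c = sample(1:50, 100, TRUE),
                           d = sample(1:5000, 100, TRUE))
    r <- ror_woolf(tabs)
    expect_equal(ror_from_ci(r$ci_low, r$ci_high), r$ror,
                 tolerance = 1e-12)
  })
})

test_that("screening emits only unexpected pairs above the case minimum", {
  cfg <- generator_config(
    n_reports = 2000, seed = 61,
    injected_signals = data.frame(drug = "L04AA23", pt = "Abortion",
                                  theta = 20))
  x <- simulate_srs(cfg)
  scr <- screen_signals(x, default_smpc(), dict = default_meddra())
  expect_s3_class(scr, "pv_screen")
  expect_true(all(scr$n_cases >= 3))
  expect_false(any(scr$expected))
  top <- scr[1, ]
  expect_equal(paste(top$drug, top$pt), "L04AA23 Abortion")
  expect_true(top$ci_low <= 20 && 20 <= top$ci_high)
  # sorted by descending ROR; supporting ids really carry drug and event
  expect_true(all(diff(scr$ror[!is.na(scr$ror)]) <= 0))
  ids <- top$report_ids[[1]]
  expect_equal(length(ids), top$a)
  expect_true(all(ids %in% x$drugs$report_id[x$drugs$code == "L04AA23"]))
})

test_that("pairs below three cases are never emitted", {
  x <- icsr_set(
    mk_reports(sprintf("r%d", 1:30)),
    dplyr::bind_rows(lapply(sprintf("r%d", 1:30), mk_drug,
                            code = "L04AA27")),
    dplyr::bind_rows(
      mk_reaction(c("r1", "r2"), "Abortion"),
      lapply(sprintf("r%d", 3:30), mk_reaction, verbatim = "Lymphopenia")
    )
  )
  x <- normalize_reactions(x, default_meddra())
  scr <- screen_signals(x, default_smpc(), dict = default_meddra())
  expect_false(any(scr$pt == "Abortion"))
})

test_that("a fully-expected dataset yields an empty screen", {
  x <- normalize_reactions(
    mk_simple_set(sprintf("r%d", 1:10), "L04AA27", "Lymphopenia"),
    default_meddra())
  scr <- screen_signals(x, default_smpc(), dict = default_meddra())
  expect_equal(nrow(scr), 0L)
  g <- glance(scr)
  expect_equal(g$n_signals, 0L)
})

test_that("tidy and glance summarize a screen in broom shapes", {
  x <- simulate_srs(generator_config(n_reports = 500, seed = 8))
  scr <- screen_signals(x, default_smpc(), dict = default_meddra())
  td <- tidy(scr)
  expect_true(all(c("drug", "pt", "n_cases", "ror", "ci_low", "ci_high")
                  %in% names(td)))
  g <- glance(scr)
  expect_equal(g$n_ref, 500L)
  expect_equal(g$n_signals, nrow(scr))
})

test_that("the serious case series reproduces the printed 19-case shape", {
  t5 <- serious_cases_fixture()
  cs <- case_series(t5)
  expect_equal(nrow(cs), 19L)
  expect_equal(sum(cs$sex == "F"), 10L)
  expect_equal(sum(cs$seriousness == "death"), 6L)
  expect_equal(sum(cs$seriousness == "life_threatening"), 11L)
  expect_equal(sum(cs$seriousness == "disability"), 2L)
  age <- attr(cs, "age_summary")
  expect_equal(c(age$median, age$q1, age$q3), c(46, 39, 52.5))
  # TTOs are realized through the encoded dates
  expect_equal(cs$tto_days[cs$report_id == "SC-14"], 1948L)
  expect_equal(cs$tto_days[cs$report_id == "SC-15"], 1214L)
  expect_equal(cs$causality[cs$report_id == "SC-07"], "possible")
})

test_that("case series on reports without qualifying criteria is empty", {
  x <- mk_simple_set(c("a", "b"), "L04AA27", "Rash",
                     seriousness = "hospitalization")
  cs <- case_series(x)
  expect_equal(nrow(cs), 0L)
  expect_equal(nrow(attr(cs, "age_summary")), 0L)
})
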