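test_that("stratified counts match the generator's truth ledger", {
  x <- simulate_srs(generator_config(n_reports = 800, seed = 11))
  led <- attr(x, "ledger")$strata
  want <- setNames(led$n, led$stratum)

  sex_tab <- stratified_counts(x, "sex")
  tot <- sex_tab[sex_tab$drug == "Total", ]
  expect_equal(tot$n[tot$level == "F"], unname(want["female"]))
  expect_equal(tot$n[tot$level == "M"], unname(want["male"]))
  expect_equal(tot$n[tot$level == "missing"], unname(want["sex_missing"]))

  ser_tab <- stratified_counts(x, "seriousness")
  tot <- ser_tab[ser_tab$drug == "Total", ]
  expect_equal(tot$n[tot$level == "serious"], unname(want["serious"]))
  expect_equal(tot$n[tot$level == "missing"],
               unname(want["seriousness_missing"]))

  age_tab <- stratified_counts(x, "age_group")
  tot <- age_tab[age_tab$drug == "Total", ]
  expect_equal(tot$n[tot$level == "adult_18_65"], unname(want["adult_18_65"]))
  expect_equal(tot$n[tot$level == "missing"], unname(want["missing"]))
})

test_that("every stratified block conserves counts exactly", {
  x <- simulate_srs(generator_config(n_reports = 500, seed = 3))
  for (stratum in c("seriousness", "sex", "age_group", "outcome")) {
    tab <- stratified_counts(x, stratum)
    sums <- tapply(tab$n, tab$drug, sum)
    totals <- tapply(tab$total, tab$drug, unique)
    expect_equal(unname(sums), unname(totals), info = stratum)
    # the Total row counts the whole set once
    expect_equal(unique(tab$total[tab$drug == "Total"]), n_reports(x))
  }
})

test_that("percentages are computed from counts and rounded half-up", {
  x <- mk_simple_set(sprintf("r%02d", 1:8), "L04AA27", "Rash",
                     seriousness = c(rep("hospitalization", 3), rep("", 5)))
  tab <- stratified_counts(x, "seriousness")
  tot <- tab[tab$drug == "Total", ]
  expect_equal(tot$pct[tot$level == "serious"], 37.5)
  # half-up at one decimal: 1/16 = 6.25% -> 6.3
  x2 <- mk_simple_set(sprintf("s%02d", 1:16), "L04AA27", "Rash",
                      seriousness = c("hospitalization", rep("", 15)))
  t2 <- stratified_counts(x2, "seriousness")
  expect_equal(t2$pct[t2$drug == "Total" & t2$level == "serious"], 6.3)
})

test_that("empty input yields an empty table with zero totals", {
  x <- icsr_set(mk_reports(character(0)), mk_drug(character(0), character(0)),
                mk_reaction(character(0), character(0)))
  expect_equal(nrow(stratified_counts(x, "sex")), 0L)
})

test_that("annual trend spans the window with explicit zeros", {
  x <- mk_simple_set("r1", "L04AA27", "Rash", receipt = "2020-12-31")
  tr <- annual_trend(x, window = c("2002-01-01", "2020-12-31"))
  expect_equal(nrow(tr), 19L)
  expect_equal(tr$n[tr$year == 2020], 1L)
  expect_equal(sum(tr$n), 1L)
  expect_true(all(tr$n[tr$year < 2020] == 0L))
})

test_that("an injected reporting peak is recovered as the argmax year", {
  w <- setNames(rep(1, 19), 2002:2020)
  w["2018"] <- 8
  x <- simulate_srs(generator_config(n_reports = 600, seed = 21,
                                     annual_weights = w))
  tr <- annual_trend(x, window = c("2002-01-01", "2020-12-31"))
  expect_equal(tr$year[which.max(tr$n)], 2018)
  expect_equal(sum(tr$n), 600L)
})

test_that("SOC is counted once per report, PT once per report per term", {
  x <- icsr_set(
    mk_reports("r1"),
    mk_drug("r1", "L04AA27"),
    mk_reaction(c("r1", "r1"), c("Pyrexia", "Asthenia"))
  )
  x <- normalize_reactions(x, default_meddra())
  prof <- soc_pt_profile(x, "L04AA27")
  soc_row <- prof[prof$level == "soc", ]
  expect_equal(nrow(soc_row), 1L)
  expect_equal(soc_row$n, 1L)
  expect_equal(sort(prof$pt[prof$level == "pt"]), c("Asthenia", "Pyrexia"))
  expect_equal(prof$n[prof$level == "pt"], c(1L, 1L))
})

test_that("profile of an unknown drug errors; zero reports give empty", {
  x <- normalize_reactions(mk_simple_set("r1", "L04AA27", "Rash"),
                           default_meddra())
  expect_error(soc_pt_profile(x, "XXX"), "unknown drug")
  empty <- soc_pt_profile(x, "L04AA23")
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "n_reports"), 0L)
})

test_that("an injected PT share is recovered within sampling error", {
  # every report carries >= 1 reaction, so a PT's share among a drug's
  # reports is the conditional probability P(PT | >= 1 reaction); pick the
  # unconditional rate p whose conditional share is 40%, then express it as
  # an odds multiplier on the background rate
  target <- 0.40
  cfg0 <- generator_config()
  p0 <- cfg0$background_event_rates[["Abortion"]]
  s_other <- prod(1 - cfg0$background_event_rates[
    names(cfg0$background_event_rates) != "Abortion"])
  p <- target * (1 - s_other) / (1 - target * s_other)
  theta <- (p / (1 - p)) / (p0 / (1 - p0))
  x <- simulate_srs(generator_config(
    n_reports = 4000, seed = 31,
    injected_signals = data.frame(drug = "L04AA23", pt = "Abortion",
                                  theta = theta)))
  prof <- soc_pt_profile(x, "L04AA23")
  share <- prof$pct[prof$level == "pt" & prof$pt == "Abortion"] / 100
  n_drug <- attr(prof, "n_reports")
  se <- sqrt(target * (1 - target) / n_drug)
  expect_lt(abs(share - target), 3 * se + 0.01)
})

test_that("profile percentages are invariant under report reordering", {
  x <- simulate_srs(generator_config(n_reports = 200, seed = 13))
  perm <- withr::with_seed(2, sample(nrow(x$reports)))
  xp <- icsr_set(x$reports[perm, ], x$drugs, x$reactions)
  a <- soc_pt_profile(x, "L04AA27")
  b <- soc_pt_profile(xp, "L04AA27")
  expect_equal(dplyr::arrange(a, .data$soc, .data$level, .data$pt),
               dplyr::arrange(b, .data$soc, .data$level, .data$pt))
})

test_that("type-7 quantiles match the sort-and-interpolate oracle", {
  expect_equal(quantile_type7(5, 0.3), 5)
  expect_equal(quantile_type7(1:5, 0.5), 3)
  expect_equal(quantile_type7(1:5, c(0.25, 0.75)), c(2, 4))
  expect_error(quantile_type7(numeric(0), 0.5), "non-missing")
  withr::with_seed(99, {
    for (i in 1:200) {
      v <- stats::rnorm(sample(1:40, 1))
      p <- stats::runif(1)
      expect_equal(quantile_type7(v, p), oracle_quantile7(v, p),
                   tolerance = 1e-12)
    }
  })
})

test_that("quantile_summary orders q1 <= median <= q3", {
  withr::with_seed(7, {
    for (i in 1:50) {
      s <- quantile_summary(stats::rlnorm(sample(2:30, 1)))
      expect_true(s$q1 <= s$median && s$median <= s$q3)
    }
  })
  expect_equal(nrow(quantile_summary(c(NA, NA))), 0L)
})

test_that("Wilson intervals behave at the boundaries and match prop.test", {
  expect_equal(proportion_ci(0, 10)$lower, 0)
  expect_equal(proportion_ci(10, 10)$upper, 1)
  ci <- proportion_ci(50, 100)
  expect_equal(ci$lower + ci$upper, 1, tolerance = 1e-12)  # symmetric about .5
  expect_error(proportion_ci(1, 0), ">= 1")
  expect_error(proportion_ci(5, 3), "in \\[0, n\\]")
  # independent route: the score interval of prop.test without correction
  withr::with_seed(17, {
    for (i in 1:50) {
      n <- sample(5:500, 1)
      k <- sample(0:n, 1)
      got <- proportion_ci(k, n)
      ref <- suppressWarnings(stats::prop.test(k, n,
                                               correct = FALSE))$conf.int
      expect_equal(c(got$lower, got$upper), as.numeric(ref),
                   tolerance = 1e-6)
    }
  })
})

test_that("the normal-approximation CI is available behind a flag", {
  got <- proportion_ci(30, 100, method = "normal")
  half <- stats::qnorm(0.975) * sqrt(0.3 * 0.7 / 100)
  expect_equal(c(got$lower, got$upper), c(0.3 - half, 0.3 + half),
               tolerance = 1e-12)
})
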