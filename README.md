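# pvsignal

Disproportionality signal detection for spontaneous adverse-drug-reaction
reports, built for pharmacovigilance analysts working with individual case
safety reports (ICSRs) — the kind of relational report/drug/reaction data
held in regional and national spontaneous reporting systems. The package was
developed around the surveillance of multiple-sclerosis disease-modifying
therapies (interferons, glatiramer acetate, natalizumab, fingolimod, and the
newer oral and monoclonal agents), but every stage is configuration-driven
and works for any drug list, reaction dictionary and label registry.

## What it computes

The pipeline covers the standard stages of an SRS safety analysis:

* **Ingestion** — strict ISO-dated CSV loading of the three-table ICSR
  dialect, inclusion rules (study window, qualifying suspected drugs, brand
  restrictions, source exclusion), and heuristic-key deduplication.
* **Descriptives** — stratified count tables (seriousness, sex, age band,
  outcome) with exact count conservation, annual trends, per-drug SOC/PT
  reaction profiles under MedDRA-style counting conventions, medians with
  IQR, and Wilson 95% confidence intervals for proportions.
* **Causality** — Naranjo questionnaire scoring with data-driven item
  weights, the published score bands (≥9 very likely, 5–8 probable, 1–4
  possible, ≤0 doubtful), and time-to-onset / time-to-resolution arithmetic.
* **Signals** — expectedness screening against an SmPC (label) registry and
  the reporting odds ratio with its Woolf confidence interval. For a
  drug–event pair with report-level 2×2 cells *a, b, c, d*:

  ROR = (a·d)/(b·c),  95% CI = exp( ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d) )

  Pairs are screened only when unexpected and supported by at least three
  cases (the *n* ≥ 3 rule). The CI is log-symmetric about the estimate, so
  `ror_from_ci()` recovers the point ROR from published bounds.
* **Simulation** — a synthetic SRS generator with report-level marginals,
  per-PT background reaction rates and *injected* drug–event signals: the
  event odds of exposed reports are multiplied by a chosen θ so the
  population ROR equals θ by construction, giving the whole pipeline a
  ground truth to recover.

## Worked example

```r
library(pvsignal)

# simulate a study-sized reporting dataset with one planted signal
cfg <- generator_config(
  n_reports = 2000, seed = 7,
  injected_signals = data.frame(drug = "L04AA23", pt = "Abortion",
                                theta = 20))
x <- simulate_srs(cfg)

# screen every drug-event pair against the label registry
scr <- screen_signals(x, default_smpc(), dict = default_meddra())
dplyr::mutate(tidy(scr)[1, ], dplyr::across(ror:ci_high, \(v) round(v, 1)))
#> # A tibble: 1 × 7
#>   drug    pt       n_cases   ror ci_low ci_high expected
#>   <chr>   <chr>      <int> <dbl>  <dbl>   <dbl> <lgl>
#> 1 L04AA23 Abortion     107  18.4   12.4    27.4 FALSE
```

The planted natalizumab–abortion pair is returned as the top signal: 107
co-reports, an estimated ROR of 18.4 whose Woolf 95% interval (12.4–27.4)
covers the injected truth of 20, and `expected = FALSE` because abortion is
absent from the drug's label registry entry. `glance(scr)` summarizes the
screen; `autoplot(scr)` draws the forest plot.

The serious-case-series path works the same way on real or fixture data:

```r
cs <- case_series(serious_cases_fixture())
attr(cs, "age_summary")
#> # A tibble: 1 × 4
#>       n    q1 median    q3
#>   <int> <dbl>  <dbl> <dbl>
#> 1    19    39     46  52.5
```

## Configuration files

Dictionaries and registries are plain YAML (`read_meddra_yaml()`,
`read_smpc_yaml()`); examples ship under `inst/extdata/`. The bundled
`default_meddra()` terminology and `default_smpc()` registry are synthetic
illustrative content so the pipeline runs end-to-end out of the box — real
analyses should supply licensed MedDRA content and registries transcribed
from current SmPCs.
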