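---
title: "Methods: disproportionality screening of spontaneous ADR reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening of spontaneous ADR reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The data and the question

A spontaneous reporting system (SRS) collects individual case safety
reports (ICSRs): one patient, one or more suspected drugs, one or more
reported reactions coded to a MedDRA-style terminology (preferred term, PT,
nested in a system organ class, SOC). SRS data carry no denominator of
exposed patients, so incidence cannot be estimated; what *can* be asked is
whether a drug–event pair is reported disproportionately often relative to
the rest of the database. `pvsignal` implements that question end to end for
relational report/drug/reaction tables, with the multiple-sclerosis
disease-modifying therapies as the bundled study configuration.

## The disproportionality model

For a drug D and canonical event term E, the reference report set is cross-
classified at the *report* level:

|            | event E | no event E |
|------------|---------|------------|
| D suspected| a       | b          |
| D not suspected | c  | d          |

Exposure means D appears as a *suspected* drug (concomitants never count);
event presence means any reaction on the report resolves to E after synonym
canonicalization. Reports with several suspected drugs enter every such
drug's exposed margin — this is the convention under which the cells still
partition the reference set for each pair separately, and it matches how
dual-suspect reports are tabulated in published stratified tables.

The reporting odds ratio and its Woolf (log-normal) interval are

$$\mathrm{ROR} = \frac{ad}{bc}, \qquad
\mathrm{CI}_{95} = \exp\!\Big(\ln \mathrm{ROR} \pm
1.96\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\Big).$$

The interval is log-symmetric about the estimate, which gives a free
validation identity: the geometric mean of the bounds recovers the point
estimate to machine precision (`ror_from_ci()`), and the same identity lets
published ROR/CI triples be checked for internal consistency.

Screening (`screen_signals()`) emits a pair only when it is **unexpected**
— the canonical PT is absent from the drug's label registry entry — and
supported by at least `min_cases = 3` co-reports. Both choices are
field-standard: expectedness confines attention to potential new risks, and
the three-case floor suppresses estimates whose CI is dominated by a single
report. `z = 1.96` is fixed (95%) and no multiplicity adjustment is
applied; the output is hypothesis-generating, not confirmatory.

**Comparator.** The reference set for the 2×2 is the in-scope report set
itself, so the implicit comparator is "the other drugs in the same analysis
stratum". If an external all-drug background is available it can simply be
included in the `icsr_set` passed as the reference; nothing in the
construction assumes the drug list is small.

**Zero cells.** With `a ≥ 3` enforced, only `c = 0` (or a degenerate `b` or
`d`) can occur. The default reports such tables as *indeterminate* (`NA`
estimate, flagged) rather than silently correcting; the Haldane–Anscombe
+0.5-to-every-cell correction is available behind `haldane = TRUE` for users
who prefer a finite estimate.

## Case-level assessment

**Naranjo.** The ten-item causality questionnaire is scored with a
data-driven weight table (`naranjo_weights()`), defaulting to the standard
instrument: items 2 and 4 score +2/−1 for yes/no, item 5 scores −1/+2
(alternative causes *absent* supports causality), item 6 scores −1/+1, the
remainder +1/0, unknown always 0. Exhaustive enumeration of all $3^{10}$
answer vectors (a test in the suite) bounds the score to $[-4, 13]$, and
the published bands — very likely ≥9, probable 5–8, possible 1–4, doubtful
≤0 — partition that range with no gaps or overlaps. Scores outside the
attainable range are rejected as errors rather than clamped.

**Onset and resolution times.** TTO is the day count from the suspected
drug's start date to the reaction's onset; TTR from onset to resolution.
Both are computed per drug–reaction pair, so a report with two suspected
drugs used in different periods yields one TTO per drug. A negative
difference is reported as a *violation record* with a missing value, never
as a negative time: it indicates a data error or a misattributed drug, and
silently dropping or flipping it would bias the summaries.

**Quantiles.** All medians and IQRs use linear interpolation at rank
$h = (n-1)p + 1$ on the sorted values (type 7, R's default). The
convention matters: on the bundled 19-case serious series the printed
median (Q1–Q3) age of 46 (39–52.5) is reproduced by type 7, whereas the
$(n+1)p$ family lands elsewhere; the case fixture pins the choice
empirically. Proportion intervals use the Wilson score construction
(well-behaved at 0 and 1 and for small counts), with the plain normal
approximation behind a flag.

**Display rounding** is half away from zero at one decimal
(`round_half_up()`), matching how published tables round; all internal
arithmetic is unrounded.

## Ingestion rules

Inclusion applies, in fixed precedence, region → reporting window →
qualifying suspected drug → brand restriction → excluded source, and each
excluded report carries exactly one primary reason so the accounting
`kept + excluded = input` is deterministic and auditable. The bundled study
configuration spans January 2002 – December 2020, lists the eleven MS
drugs, restricts cladribine to its MS-indicated brand, and excludes
literature reports.

Deduplication uses the standard SRS heuristic key — sex, rounded age,
sorted suspected drug codes, sorted canonical PTs, earliest reaction onset
— keeping the earliest-received report of each group (ties broken by
lexicographic id). The key is deliberately exposed through the dictionary
argument so stricter or looser keys can be evaluated; no probabilistic
linkage is attempted. Dates are parsed strictly as ISO-8601: regulatory
exports vary enough that a hard parse error beats a silent misparse.

Missing values are data, not absences: stratified tables carry an explicit
`missing` column per block, a report is serious iff its criteria set is
non-empty (with `NA` meaning *unknown seriousness*, distinct from the empty
set), and unknown reaction terms default to pass-through-with-flag so
descriptive counts never silently shrink. When one seriousness label must
be printed per case, precedence is death > life-threatening > disability >
congenital anomaly > hospitalization > other medically important — the
usual regulatory severity ordering.

## The synthetic generator and what it does (not) show

`simulate_srs()` draws reports whose marginals mirror the published
regional study set: 1,119 reports by default, drug shares proportional to
the printed per-drug totals, 3/1,119 dual-suspect reports, 72.3% female
with 1.1% sex missingness, ages concentrated in the 18–65 band with 6.8%
missing, per-drug serious shares averaging ≈26.5%, and uniform annual
weights (no trend shape is assumed; a peak can be injected through
`annual_weights`). Onset times are lognormal per drug, parameterized from
the published medians (most drugs a few hundred days; alemtuzumab 27 days;
interferon β-1b 1,578 days). Outcome frequencies are not published for the
regional set, so a plausible SRS mix was fixed once (about half of reports
resolved or improved) and is exposed in the config.

Reactions are independent per-PT Bernoulli draws with background rates
taken from the printed overall PT frequencies. An injected signal
multiplies the event *odds* for exposed reports, so the population ROR of
the pair equals θ by construction. Two subtleties:

* **Rejection resampling.** Every report must carry ≥1 reaction, so empty
  draws are resampled. Conditioning on "≥1 reaction" scales the event odds
  of pair E by $1/(1-S)$ where $S$ is the probability of no *other* PT —
  identical in the exposed and unexposed arms because exposure only alters
  E itself. The injected ROR therefore survives the conditioning exactly,
  which is what the coverage test relies on.
* **Shares vs rates.** A PT's share among a drug's reports is the
  *conditional* probability given ≥1 reaction; tests that target a share
  derive the required unconditional rate from the generator's own
  parameters rather than equating the two.

Each emitted dataset carries a *truth ledger* — realized 2×2 cells of every
injected pair, stratum tallies, per-drug, per-PT and per-year counts, and
raw row counts — and `ledger_audit()` recounts all of it from the emitted
tables by literal per-report scans, so any tampering (a dropped reaction
row, an edited field) is detected.

What passing tests on this generator **do** show: the counting conventions,
the estimator and its CI, the screening rules, and the ingestion accounting
are correct, and the Woolf interval attains nominal coverage when its
assumptions hold. What they **do not** show: real SRS data violate the
generator's independence assumptions (event co-occurrence, drug-specific
reaction profiles beyond injected pairs, reporting waves, under- and
over-reporting, duplicate reports more devious than clones). Results on
real data inherit all the usual caveats of disproportionality analysis; a
flagged pair is a hypothesis, not a risk estimate.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations for a
single CPU: 500 replicates of 2,000 reports for CI coverage of an injected
θ = 20 (the estimator sees expected exposed-case counts of ≈150, where the
log-normal approximation is comfortably accurate), 100 replicates for null
calibration (pooling ≈19,000 eligible pairs), 40 replicates per θ ∈ {2, 5,
20} for median recovery, and ≥1,000 random instances per brute-force oracle
comparison. Larger runs change none of the logic — only the Monte Carlo
error.

Other numerical choices: all counting is integer and conservation checks
are exact equalities, never tolerances; quantile and CI comparisons in the
suite use `1e-12` relative tolerance against independent closed forms;
`round_half_up()` adds `sqrt(.Machine$double.eps)` before flooring to
absorb binary representation error on exact halves; and the Woolf
log-symmetry identity is asserted to machine precision on random tables.

## Known limitations

* PT-level screening only; SOC-level screening and Bayesian shrinkage
  estimators (BCPNN, EBGM) are out of scope, as is PRR.
* The bundled dictionary and label registry are small synthetic
  illustrations; real analyses must supply licensed MedDRA content and
  registries transcribed from current SmPCs.
* Deduplication is deterministic-key only.
* The generator models reaction co-occurrence as independent given the
  report, which understates the clustering seen in real reports.
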