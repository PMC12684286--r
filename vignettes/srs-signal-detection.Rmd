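---
title: "Signal detection in spontaneous reporting databases with srsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal detection in spontaneous reporting databases with srsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srsignal)
```

## The problem

Spontaneous reporting systems (SRS) such as Japan's JADER and the FDA's
FAERS collect individual case safety reports (ICSRs): one report
describes one patient, the drugs they received, and the adverse events
observed. Because an SRS has no denominator population, drug safety
screening works by *disproportionality*: is the target event reported
together with the target drug more often than the database's own
reporting background would predict? srsignal implements this screening
workflow end to end — table ingestion for both database dialects,
de-duplication, drug–event pair expansion, four disproportionality
metrics with their conventional signal thresholds, stratified and
sensitivity variants, and a Weibull time-to-onset model — together with
a synthetic-SRS generator whose ground truth makes every stage testable
without multi-gigabyte database downloads. The motivating application is
the screening of fibrates (pemafibrate, fenofibrate, bezafibrate)
against the biliary adverse events grouped under the MedDRA high-level
term "Cholecystitis and cholelithiasis" (code 10008616), and the
package defaults reflect that use case; every component is, however,
plain configuration (drug lexicon, target PT list), not hard-wired.

A disproportionality signal indicates disproportionate *reporting*, not
causality; the package computes screening statistics, nothing more.

## Data model

The unit of counting is the **drug–event pair**: each report is expanded
into all combinations of its drug entries and event entries
(`expand_pairs()`), so a report with two drugs and three events yields
six pairs. Pairs retain the reported drug role (primary suspect,
secondary suspect, concomitant, interacting; JADER has a single
undifferentiated suspect role), enabling the primary-suspect-only
sensitivity analysis. Agent-level pair counts are not mutually exclusive
— one report listing two fibrates contributes pairs to both — so
overall totals are reported as unique ICSRs (`count_unique_icsrs()`).

Dialect specifics handled by the readers:

* **JADER** (`read_jader_tables()`): comma-separated tables in a legacy
  Japanese encoding, decoded as CP932 (the Shift-JIS superset the PMDA
  uses). Undecodable bytes are a hard error naming file and line;
  silently substituting characters would corrupt drug names. Age,
  height and weight arrive as bands ("60歳代", "160cm台",
  "60kg台"); they are kept banded, never imputed to a point value
  except where a stratification rule explicitly takes band midpoints.
* **FAERS** (`read_faers_tables()`): `$`-delimited ASCII with a header
  line. Rows are parsed positionally; empty trailing fields are
  preserved. Successive versions of one case are removed by
  `dedup_faers()`, keeping the highest `caseversion` per `caseid`; a
  missing version counts as 0 and ties are broken toward the larger
  `primaryid` (the later submission). The rule is idempotent.

Dates are **partial dates**: year, optional month, optional day
(`pd_parse()`). Only complete, valid calendar dates enter time-to-onset
analysis; month-only dates are excluded, never imputed to the first of
the month.

## Disproportionality metrics

All four metrics are computed from the 2×2 table of pair counts
(`n11` drug-and-event, `n12` drug-only, `n21` event-only, `n22`
neither):

* **ROR** `= (n11 n22)/(n12 n21)` with the log-scale Wald interval
  `exp(log ROR ± z √(1/n11 + 1/n12 + 1/n21 + 1/n22))`, plus a
  two-sided Fisher exact p-value. The construction makes the point
  estimate the geometric mean of the interval bounds — a property the
  test suite exploits to verify interval construction against published
  estimate/interval triples.
* **PRR** `= [n11/(n11+n12)] / [n21/(n21+n22)]` with the analogous
  Wald interval and a Yates-corrected chi-square (the MHRA convention;
  `yates = FALSE` disables the correction).
* **IC** (BCPNN information component)
  `= log2((n11 + 0.5)/(E + 0.5))` with `E = n1+ n+1 / n++`; the
  credibility interval is taken from the
  `Gamma(n11 + 0.5, E + 0.5)` posterior of the rate ratio on the log2
  scale. This shrinkage form with exact gamma quantiles is the default;
  a closed-form approximation of the bounds is available via
  `variant = "approx"`.
* **EBGM** (Gamma–Poisson Shrinker): the rate ratio λ of observed to
  expected reporting gets the DuMouchel two-component gamma mixture
  prior `w·Gamma(a1, b1) + (1−w)·Gamma(a2, b2)`; hyperparameters are
  fitted by maximizing the marginal (negative-binomial mixture)
  likelihood over the whole drug × event cell universe, and the
  per-cell posterior — another two-component gamma mixture — yields
  `EBGM = 2^{E[log2 λ]}` (digamma form; `estimate = "mean"` switches
  to the posterior mean) and percentile bounds by root-finding on the
  mixture CDF. Expected counts may be stratified:
  `E = Σ_s n_d+(s) n_+e(s) / n_++(s)`, with sex × age the default
  stratification, matching practice for JADER-style analyses.

Signal thresholds (`apply_signal_rules()`) follow the conventional
definitions exactly, including strictness: ROR — `n11 ≥ 3` and
`ROR025 > 1`; PRR — `n11 ≥ 3`, `PRR025 > 2` (strict) and `χ² > 4`;
IC — `IC025 > 0` (strict); EBGM — `EBGM05 ≥ 2.0` (inclusive). No
multiplicity correction is applied: these are fixed per-metric
screening thresholds, not hypothesis tests with error-rate control.

### Numerical and degenerate-input choices

* **Zero cells** make ROR/PRR undefined. The default is an explicit
  undefined-result marker rather than a silent Haldane–Anscombe +0.5
  correction (`continuity = TRUE` opts in). Rationale: the `n11 ≥ 3`
  rule makes zero-cell tables non-signals regardless, and a marker is
  honest about why.
* **GPS optimization** runs Nelder–Mead on
  `(logit w, log a1, log b1, log a2, log b2)` from the classical
  initialization `(1/3, 0.2, 0.1, 2, 4)` plus four seeded random
  restarts, keeping the best optimum. When the data are consistent with
  a single gamma prior the two components are not separately
  identified (one component can split or vanish); identifiable
  functionals — the prior moments and all posterior summaries — are
  stable, and that is what the tests check.
* **Fisher's exact test** delegates to `stats::fisher.test()`; the test
  suite verifies it against an independent full hypergeometric
  enumeration on hundreds of random tables.

## Pair-level versus report-level tables

The classical 2×2 table counts pairs (`unit = "pair"`), and that is the
default everywhere. The generator's association parameter θ, however,
is defined on the *report level*: it multiplies the odds that the event
occurs in a report exposed to the drug, so the report-level odds ratio
equals θ exactly. The pair-level ROR is not the same estimand — the
pair expansion weights reports by their drug and event counts, and odds
ratios are not collapsible over that weighting — though the two agree
closely when exposure prevalence and event rates are low.
`build_contingency(..., unit = "icsr")` therefore builds the
report-level table, and the parameter-recovery validation uses it so
that the estimand is exact; the pipeline's headline tables stay
pair-based.

## Stratified and sensitivity analyses

`stratified_analysis()` re-derives the pair universe inside each level
of sex (male/female), age (≥60 versus 20–50 years, resolved on the
literal decade band: "20s"–"50s" versus "60s" and above; other bands
are excluded), or BMI (≥25 versus <25). BMI is computed from band
midpoints — `mid([low, high)) = (low + high)/2` for the 10-cm and
10-kg bands — and reports missing sex, a resolvable age band, or either
anthropometry band are excluded from the corresponding stratification,
never imputed. `run_sensitivity()` restricts the pair universe to
primary-suspect roles; because JADER does not split primary from
secondary suspects, its single suspect role is treated as primary
suspect there (switchable via `include_unspecified_suspect`).

## Time-to-onset model

Time to onset is `days = (onset − therapy start) + 1`; the +1 keeps
same-day onsets at one day so the log-likelihood is defined. Records
with an incomplete start date, incomplete onset, or onset before start
are excluded, with counts logged by reason. The Weibull fit maximizes
the log-likelihood via the one-dimensional profile equation for the
shape — the profile score is strictly increasing, so the root is
unique; `uniroot()` solves a single fit and a vectorized, safeguarded
Newton iteration refits the thousands of bootstrap resamples — after
which the scale has the closed form `α = mean(t^β)^{1/β}` (computed on
rescaled data to avoid overflow). Confidence intervals are percentile
bootstrap with `B = 2000` resamples by default and a recorded seed;
resamples whose fit degenerates (e.g. all values identical) are redrawn
and counted, and more than 10% failures is an error. Percentile
intervals are the default, as the simplest reading of "bootstrapped
CIs"; they are, however, anti-conservative for the shape at very small
n — the shape MLE is biased upward and skewed, and simulation at
n = 17 shows about 84% coverage for a nominal 95% interval, a figure
reproduced by independent implementations of the same procedure.
`type = "bca"` applies the bias-corrected and accelerated adjustment
(jackknife acceleration), which restores near-nominal coverage
(about 90% observed at n = 17); the BCa interval is what the package's
coverage validation exercises. Quartiles use linear interpolation
between order
statistics (quantile type 7). The shape interval classifies the hazard
pattern: lower bound >1 wear-out, upper bound <1 early failure,
otherwise random. A report with several qualifying events contributes
one record per event by default (`multiple = "earliest"` collapses to
the first onset).

## The synthetic-SRS generator

`simulate_srs()` draws datasets whose ground truth is known and renders
them in both dialects, byte-identically for identical configurations.
Per report: demographics from configured marginals; independent drug
exposures; events with odds `baseline_odds × Π θ(d, e)` over exposed
drugs; onsets for configured (drug, event) combinations at therapy
start plus a Weibull draw rounded half-up to whole days (floored at 0,
so SRS day granularity is respected before the pipeline's +1); day
components blanked with the configured probability; FAERS cases
duplicated with incremented case versions with the configured
probability, as exact copies so that the dedup rule is isolated.
θ acts on the odds rather than the probability scale precisely so that
the population report-level ROR equals θ and parameter recovery is a
clean pass/fail criterion.

The default scenario (`default_sim_config()`) encodes the study
conditions the package validates under: 50,000 reports; the three
fibrates (2–5% exposure) plus ten background drugs (12%); the fourteen
target biliary PTs (three attested terms at baseline odds 0.010,
eleven placeholders at 0.003) plus eight background events (0.12); one
ground-truth association, pemafibrate–cholelithiasis with θ = 4; a
pemafibrate time-to-onset law with scale 469.66 days and shape 1.59;
67.9% male and 67.9% aged ≥60 (the reported fibrate case profile);
39.3% of day components missing (published onset completeness was
60.7%); and 10% duplicated FAERS cases. Fibrate exposure probabilities
are far above real-world reporting prevalence by design: they populate
the target cells well at a simulation size a test suite can afford.

What the generator deliberately does **not** emulate: under-reporting
dynamics, the Weber effect and notoriety bias, correlated co-exposures
(polypharmacy structure), event co-occurrence beyond shared drug
effects, real MedDRA coding noise, and free-text drug-name variants
beyond the configured lexicon. Passing tests therefore demonstrate
correctness of the computations under a clean generative model, not
robustness to the biases of real pharmacovigilance data.

## Validation problem sizes

The shipped test suite validates, among other properties: interval
construction against published estimate/CI triples (geometric-mean
consistency to 2 decimals); Fisher p-values against full enumeration on
500 random tables with totals ≤200; GPS posterior percentiles against
10⁶-draw Monte-Carlo sampling (within 0.01 on λ); 95% ROR interval
coverage of θ = 4 in ≥90 of 100 seeded replicates at 50,000 reports,
with all four signal rules firing at θ = 8 and none at θ = 1; Weibull
recovery of (α, β) = (469.66, 1.59) within 3% from 10⁴ draws; and
BCa bootstrap shape-interval coverage within [0.88, 0.99] over 500
replicates at n = 17, B = 2000. Generator-level estimand checks
(log-ROR centering) run at 12–30 replicates of 20,000 reports — sizes
chosen to keep the full suite comfortably interactive while leaving
the Monte-Carlo error well inside the asserted bounds.

## Known limitations

* The shipped fourteen-PT list contains eleven clearly marked
  placeholder terms; analysing real data requires the licensed MedDRA
  PT list for HLT 10008616.
* Drug matching is exact after normalization (uppercase, trimmed,
  whitespace collapsed) over an explicit synonym lexicon; no
  fuzzy or active-ingredient normalization.
* No censoring-aware survival modelling: the Weibull fit uses observed
  onsets only, and discontinuation or dose changes are not modelled.
* Unstratified EBGM for FAERS-style data is computed only on request,
  with a warning, since expected counts without stratification absorb
  no demographic reporting heterogeneity.
* The JADER column map follows the PMDA layout for the fields used
  here; extracts with different headers are supported by overriding
  the column map.
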