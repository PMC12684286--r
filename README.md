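# srsignal

Signal detection in spontaneous adverse-event reporting databases.

Spontaneous reporting systems (SRS) such as Japan's JADER and the FDA's
FAERS collect individual case safety reports (ICSRs) but have no
denominator population, so post-marketing drug-safety screening relies
on *disproportionality*: is a drug–event combination reported more
often than the database's own background predicts? `srsignal`
implements that workflow for pharmacoepidemiologists and
pharmacovigilance analysts:

* **Ingestion** of both dialects — JADER-style CP932 CSV tables and
  FAERS-style `$`-delimited quarterly ASCII — with FAERS case-version
  de-duplication, case-level merging, lexicon-based drug matching, and
  drug–event pair expansion.
* **Four disproportionality metrics** on the 2×2 pair table
  (`n11, n12, n21, n22`), with their conventional signal rules:
  - ROR `= n11·n22 / (n12·n21)`; signal if `n11 ≥ 3` and `ROR025 > 1`
    (log-scale Wald interval, Fisher exact p);
  - PRR `= [n11/(n11+n12)] / [n21/(n21+n22)]`; signal if `n11 ≥ 3`,
    `PRR025 > 2` and Yates χ² > 4;
  - BCPNN information component
    `IC = log2((n11+½)/(E+½))`, `E = n1+·n+1/n++`, with gamma-posterior
    credibility bounds; signal if `IC025 > 0`;
  - Gamma–Poisson Shrinker `EBGM = 2^{E[log2 λ]}` under the DuMouchel
    mixture prior `w·Γ(a1,b1) + (1−w)·Γ(a2,b2)` fitted by marginal
    maximum likelihood over the whole drug × event grid, with
    optionally stratified expected counts; signal if `EBGM05 ≥ 2.0`.
* **Stratified** (sex, age ≥60 vs 20–50, BMI ≥25 vs <25 from banded
  anthropometry) and **sensitivity** (primary-suspect-only) analyses.
* **Weibull time-to-onset** modelling: `days = onset − start + 1`,
  maximum likelihood via the one-dimensional profile equation for the
  shape, nonparametric bootstrap intervals (percentile or BCa), and
  hazard-pattern classification (wear-out / random / early failure).
* A **synthetic-SRS generator** with known ground truth (association
  strength θ on the odds scale, demographics, partial-date
  missingness, FAERS duplicate versions) that renders both dialects,
  so the whole pipeline is testable without database downloads.

The default configuration mirrors a fibrate / biliary-event screening
(pemafibrate, fenofibrate, bezafibrate against the preferred terms
under the MedDRA HLT "Cholecystitis and cholelithiasis"), but drug
lexicon and target event list are plain configuration.

## Worked example

```r
library(srsignal)

# a synthetic JADER-like dataset with a known pemafibrate association
cfg   <- default_sim_config(n_reports = 50000, theta = 4, seed = 7)
sim   <- simulate_srs(cfg)
cases <- merge_case_level(sim$jader, "jader")
pairs <- expand_pairs(cases)

disprop(pairs, "pemafibrate", "10008629", unit = "icsr")
#> Disproportionality analysis [pemafibrate vs 1 target PT(s)]  (unit: icsr)
#> n11 = 82 | unique ICSRs = 82
#> ROR = 3.24  [2.54, 4.14]  (95% interval)
#>   p_value = 5.5e-17
#> PRR = 3.13  [2.47, 3.95]  (95% interval)
#>   chi_square = 97
#> IC = 1.44  [1.11, 1.73]  (95% interval)
#>   expected = 30
#> signals (n11 = 82): ROR yes | PRR yes | IC yes | EBGM no
```

The report-level reporting odds ratio estimates the generative θ = 4
(its 95% interval covers the truth here), and ROR, PRR and IC all flag
the association. EBGM is only computed when the Gamma–Poisson prior is
fitted over the pair universe (`gps = TRUE`), as `run_primary()` does:

```r
tab <- run_primary(cases)         # per-drug rows + all-fibrates row
tab[, c("drug", "n_pairs", "n_icsr", "n11", "ror", "ebgm")]

set.seed(7)
fit <- tto_weibull(rweibull(17, shape = 1.59, scale = 469.66),
                   B = 2000, seed = 7)
fit
#> Weibull time-to-onset model (n = 17)
#>   shape beta  = 1.77 [1.12-3.54]
#>   scale alpha = 542.49 days [392.14-671.96]
#>   median TTO  = 492.6 days [332.93-678.92] (IQR 332.9-678.9, range 27.7792-869.557)
#>   hazard pattern: wear_out
```

Here the bootstrap lower bound of the shape exceeds 1, so the hazard is
classified as increasing with treatment duration ("wear-out"): late
onsets dominate. At `n = 17` that call rests on few observations, which
is exactly why the classification rule is interval-based rather than
point-estimate-based.

## Command line

A thin wrapper over the same functions ships in `inst/cli/`:

```sh
Rscript inst/cli/srsignal.R simulate --seed 1 --out data/
Rscript inst/cli/srsignal.R all --config cfg.yaml --seed 1 --out results/
```

## Caveats

Disproportionality indicates disproportionate *reporting*, never
incidence or causality. The shipped 14-term biliary PT list contains
placeholders (MedDRA is licensed); supply the licensed PT list before
analysing real data. See the methods vignette
(`vignettes/srs-signal-detection.Rmd`) for the models, assumptions,
numerical choices and known limitations.
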