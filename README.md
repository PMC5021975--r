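# seawas

Season-wide association scans of birth month and disease risk, with a
permutation test for replicating risk-curve patterns across institutions.

## What this is for

Birth month is a proxy for seasonal exposures around gestation and birth
(maternal influenza, sunlight/vitamin D, allergens). A season-wide
association study scans every diagnosis code in an EHR-derived cohort and
asks whether patients carrying the code have a different birth-month
distribution than the population. This package is for biostatisticians and
clinical informaticians who want to run such scans on flat patient /
diagnosis extracts, control the false discovery rate across the phenome,
and — the part single-site studies cannot do — test whether a condition's
birth-month risk *pattern* replicates at a second institution.

## The statistics

For one condition, with `c_m` cases and `n_m` cohort patients born in
month `m` (`C`, `N` the totals):

- **Risk curve.** `RR_m = (c_m/n_m) / ((C−c_m)/(N−n_m))` — risk for births
  in month `m` versus all other months — with Katz log-method confidence
  intervals and a Haldane–Anscombe 0.5-cell correction when a case cell is
  empty.
- **Association test.** Pearson chi-squared on the 2 × 12 case/non-case by
  birth-month table (df = 11), restricted to conditions with ≥ 1000 cases;
  Benjamini–Hochberg adjustment across exactly the tested set.
- **Replication test.** For a condition present at both institutions, the
  Pearson correlation `r` between the two 12-point RR curves is compared
  against an empirical null built by shuffling one curve's months
  (B = 1000 permutations); the p-value is the fraction of null
  correlations strictly exceeding `r`, reported as `"p < 0.001"` when the
  count is zero.

A synthetic-cohort generator injects known multiplicative cosine effects,
`p_m = p0 (1 + A cos(2π(m − φ)/12))`, into two-institution designs
(shared, independent, or null effects) so that calibration and power are
testable without any real patient data.

## Worked example

Two 200,000-patient institutions sharing two real effects — coronary
artery disease (`CAD`, p0 = 0.05, amplitude 0.08, January peak) and
hypertension (`HTN`, p0 = 0.10, amplitude 0.04, December peak) — plus ten
month-independent null conditions:

```r
library(seawas)
pop <- population_spec(200000)
effects <- list(effect_spec("CAD", 0.05, 0.08, peak_month_phi = 1),
                effect_spec("HTN", 0.10, 0.04, peak_month_phi = 12))
pair <- generate_pair(effects, "shared", list(pop, pop), seed = 2024,
                      null_conditions = 10)
scan_a <- run_scan(pair[[1]])
scan_b <- run_scan(pair[[2]])
scan_a[, c("condition_code", "n_cases", "p_raw", "p_fdr", "max_rr", "max_rr_month")]
#>    condition_code n_cases    p_raw    p_fdr max_rr max_rr_month
#> 1             CAD   10031 2.16e-06 2.16e-05   1.16           12
#> 2             HTN   19838 1.46e-01 7.29e-01   1.06            2
#> 3     NULLCOND002    1010 8.51e-01 9.31e-01   1.16           11
#> ...
```

`CAD` is phenome-wide significant at site A (FDR-adjusted p = 2.2e-05)
with its peak risk estimated in December–January; the ten null conditions
are not. The cross-institution pattern test then compares the curves:

```r
shared <- shared_condition_set(scan_a, scan_b, 1000)
rep <- replicate_all(scan_a, scan_b, shared, B = 1000, seed = 2024)
build_summary_table(scan_a, scan_b, rep)[, c("condition_code",
    "high_month_a", "high_month_b", "max_rr_a", "max_rr_b",
    "p_replication_display")]
#>   condition_code high_month_a high_month_b max_rr_a max_rr_b p_replication_display
#> 1            HTN            2            2     1.06     1.08                 0.004
#> 2            CAD           12            1     1.16     1.09                 0.009
#> 3    NULLCOND004           12            3     1.07     1.08                 0.253
#> ...
```

Both injected effects replicate (permutation p = 0.004 and 0.009) even
though `HTN` was not phenome-wide significant at site A and `CAD`'s
peak month differs by one between sites — the curve-level test sees the
shared pattern that single-month extrema miss. No null condition
replicates. `manhattan_data()`, `overlay_table()` (e.g. against monthly
flu-peak counts or serum vitamin D) and `compare_demographics()` produce
the remaining publication-style outputs, and `inst/scripts/seawas.R`
exposes `simulate | scan | replicate | report` subcommands for shell use.

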