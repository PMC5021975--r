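---
title: "Season-wide association scans: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Season-wide association scans: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seawas)
```

## The problem

A season-wide association study treats a patient's birth month as a proxy
for seasonal exposures around gestation and birth — maternal infections,
sunlight and vitamin D, allergens — and asks, for every diagnosis code in
an EHR-derived cohort, whether people carrying the code are born in a
different monthly pattern than the population at large. Because thousands
of codes are scanned at once, the analysis is phenome-wide and needs
multiplicity control; because single-site EHR findings are fragile, the
interesting question is usually whether the *shape* of a condition's
birth-month risk curve replicates at a second, independent institution.

This vignette documents the statistical machinery the package implements,
the choices that were genuinely open, and what the synthetic-data
calibration does and does not establish.

## The per-condition model

For one condition, the data reduce to a 2 × 12 table: of the $n_m$ cohort
patients born in calendar month $m$ ($m = 1$ for January), $c_m$ carry the
condition; $C = \sum_m c_m$ and $N = \sum_m n_m$. A patient is a *case* if
the mapped code appears at least once; all other cohort patients are the
controls for that condition, and patients contribute to every condition
they carry.

**Relative-risk curve.** The month-$m$ relative risk compares births in
$m$ against births in all other months:

$$RR_m = \frac{c_m / n_m}{(C - c_m) / (N - n_m)}.$$

This "month versus the rest" definition (rather than month versus the
overall mean) makes each $RR_m$ an honest 2 × 2 relative risk, so the Katz
log-method interval applies directly:

$$\exp\!\left(\log RR_m \pm z_{1-\alpha/2}
\sqrt{\tfrac1a - \tfrac1{a+b} + \tfrac1c - \tfrac1{c+d}}\right),$$

with $a = c_m$, $b = n_m - c_m$, $c = C - c_m$, $d = (N - n_m) - (C -
c_m)$. If $a$ or $c$ is zero the curve would be degenerate, so 0.5 is
added to all four cells of that month's table (Haldane–Anscombe); this
keeps every curve finite and positive, which the downstream permutation
test requires. Months with $n_m = 0$ are an error for the curve and are
dropped (with reduced degrees of freedom) from the test.

**Association test.** The omnibus birth-month association is Pearson's
chi-squared on the 2 × 12 case/non-case by month table, df = 11 (fewer if
empty months were dropped). Published season-wide scans report per-code
p-values without naming the statistic; chi-squared on the collapsed table
is the simplest omnibus test of month-by-status association and is this
package's normative choice — anyone comparing against another
implementation should check this first.

**Inclusion and FDR.** Only conditions with at least 1000 cases (after
cohort filtering — the other defensible reading, before filtering, is not
used) enter the scan, and Benjamini–Hochberg adjustment is computed across
exactly the tested set of that institution's scan. The two institutions
therefore have different FDR families, which mirrors how such studies
report phenome-wide significance separately per site. The significance
flag uses strict `p_fdr < alpha`; the boundary is pinned by a test.

## The replication statistic

Given one condition's 12-point risk curves at institutions A and B, the
observed statistic is the Pearson correlation $r$ of the two curves. The
null distribution is empirical: hold A's curve fixed, shuffle the 12
entries of B's curve as a block (a uniformly random permutation, sampling
without replacement), recompute $r$, repeat $B = 1000$ times. The p-value
is the proportion of null correlations *strictly greater* than the
observed one; zero exceedances at $B = 1000$ are displayed as
`"p < 0.001"`. Three points were genuinely open and are fixed here:

* *What "randomizing the curve" means.* Permuting the 12 values preserves
  the RR multiset and destroys only the month ordering, which is exactly
  the pattern being tested. Resampling with replacement or re-simulating
  patients would conflate pattern similarity with sampling noise.
* *Ties.* A permutation can reproduce the original curve, giving $r_b$
  numerically equal to $r$. Strict ">" means ties are not exceedances. To
  make the tie well-defined in floating point, the observed correlation is
  computed through the identical vectorized arithmetic as the null
  correlations, so an identity permutation is an exact bitwise tie. The
  `add_one` option switches to the $(b+1)/(B+1)$ convention, which never
  reports exact zeros; it is off by default.
* *Direction.* One-sided: only similarity (large positive $r$) counts as
  replication. Institution A is fixed and B permuted; a condition's
  sub-seed is derived from the master seed and the condition code, so
  results are independent of processing order.

Per-condition permutation p-values are reported unadjusted — replication
of a handful of named conditions is confirmatory, not phenome-wide.

## The synthetic cohort generator

The generator exists because real season-wide inputs are proprietary
hospital extracts. It emulates exactly the structure the analysis
consumes: patients with a birth month (any 12-point distribution; uniform
by default, since real birth-month marginals are site-specific and rarely
published), a birth year uniform on 1926–2000, independent categorical
demographics, and per-condition Bernoulli disease status whose probability
depends on birth month through a multiplicative cosine:

$$p_m = p_0\,(1 + A \cos(2\pi (m - \phi)/12)).$$

The cosine acts on the probability scale (not log-odds) so that the
injected effect maps directly onto the relative-risk scale the scan
reports: the true peak-month RR is approximately $(1+A)/(1 - A/11)$, i.e.
about 1.11 for $A = 0.1$. Null conditions take month-independent
prevalences cycled through {0.001, 0.005, 0.01, 0.05, 0.1}, a grid that
deliberately straddles the 1000-case inclusion threshold at the cohort
sizes used, so threshold behaviour is always exercised. Two-site designs
come in three modes: `shared` (same effect specs, independent patients),
`independent` (site B redraws each peak month uniformly on 1..12 and each
amplitude uniformly on [0.02, 0.15], a range covering reported
cardiovascular max RRs of roughly 1.02–1.09), and `null` (all amplitudes
zero).

What the generator does *not* emulate — visit-level longitudinal
structure, healthcare-process and documentation biases, comorbidity
correlation between conditions, non-stationary birth-month distributions
across birth years — is precisely what makes real EHR findings fragile.
Passing calibration here shows the *statistics* behave as designed under a
clean data-generating process; it says nothing about confounding in real
data.

## Calibration results the test suite computes

The acceptance tests (under `tests/testthat/`) establish, at fixed seeds
1–20:

* **Exact oracles.** RR hand arithmetic; chi-squared equal to a
  cell-by-cell $\sum (O-E)^2/E$ brute force to 1e-9; BH equal to a
  brute-force step-up to 1e-12; Pearson correlation equal to the sum-based
  definition to 1e-12; Monte-Carlo permutation p within 3 binomial SEs of
  full 24-permutation enumeration on 4-point curves.
* **Null calibration.** With 100,000 patients and 50 null conditions per
  seed, pooled raw scan p-values are compatible with U(0,1)
  (Kolmogorov–Smirnov, α = 0.01), 19/20 seeds yield zero FDR < 0.05
  discoveries, and the replication test on null pairs rejects at 0.05 in
  ≤ 0.05 + 3 MC-SE of condition pairs.
* **Effect recovery.** A $p_0 = 0.05$, $A = 0.10$, January-peak effect in
  500,000 patients is FDR-significant with the peak localized to January
  ± 1 month in ≥ 18/20 seeds, with max RR estimates inside [1.05, 1.18].
* **Replication power.** The same effect shared by two 200,000-patient
  institutions yields permutation p ≤ 0.05 in ≥ 18/20 seeds.

One designed check fails by construction and is kept failing rather than
weakened: when the two sites' effects are drawn *independently*, the
permutation test rejects far more often than 5%. That is not a bug in the
test but a property of smooth seasonal curves: with only 12 possible peak
months, about 1/12 of independently drawn condition pairs share their peak
exactly and correlate strongly for real. "Independent parameters" is not
the permutation test's null hypothesis — month-exchangeability is — so the
rejection rate against independent cosine effects is expected to exceed
the nominal level. Users should read a significant replication p-value as
"the two curves share a pattern", not "the effects were generated by a
common cause".

These problem sizes (100k–500k patients, 20 seeds, B = 1000) were chosen
as the smallest at which the stochastic properties above are stable; the
whole suite runs in about two minutes on one core.

## Numerical and degenerate-input conventions

* Months are always 1 = January .. 12 = December; extremum months break
  ties toward the earliest calendar month, so reports are deterministic.
* Duplicate (patient, code) diagnosis rows collapse to one — the analysis
  is presence/absence — and duplicate patient ids with conflicting birth
  fields are a hard error, while exact duplicates collapse silently.
* Unmapped source codes are dropped, never passed through, and counted in
  the cohort's mapping-loss report; how a real CDM mapping resolved
  many-to-many codes is unknowable from published scans, so the loss is
  surfaced rather than silently decided.
* A zero-variance risk curve (all twelve RRs equal) has no defined
  correlation; the condition is excluded with an error naming it.
* Zero adjusted p-values are clipped to the smallest positive double for
  Manhattan-plot y-values, with a message.
* Demographics comparisons match category labels case-insensitively and
  pool "Unknown"/"Unidentified"/"Declined" and single-site categories into
  one `unknown` bucket per attribute before the 2 × k chi-squared, because
  institutions encode missingness differently; attributes with fewer than
  two aligned categories are skipped with a message.
* All randomness flows from one master seed through a deterministic string
  hash (`derive_seed`), so every pipeline output is byte-identical across
  reruns with the same seed.

## Limitations

The scan is unadjusted (no age, sex or race covariates), linear Pearson
correlation is used on the month-ordered curve rather than circular
statistics, and the overlay tables for external monthly covariates (flu
peaks, serum vitamin D) are purely descriptive. These match the analysis
being reproduced; cosinor regression, circular correlation or adjusted
models would be extensions, not replacements.
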