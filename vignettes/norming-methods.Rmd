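---
title: "Methods: regression-based norming for the 50-item Stroop test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regression-based norming for the 50-item Stroop test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stroopnorm)
```

This vignette documents the statistical procedure the package implements, the
choices made where the design was genuinely open, and the limits of what the
synthetic-data tests can show.

## The norming model

Each of the twelve performance indices (task times T1–T4 in seconds, error
counts E2–E4 out of 50, and the six zero-floored difference indices) is
modelled in a healthy reference cohort by ordinary least squares on
demographics:

$$y = \beta_0 + \beta_s\,\mathrm{sex} + \beta_a\, (f_a(\mathrm{age}) - \bar f_a)
      + \beta_e\, (f_e(\mathrm{edu}) - \bar f_e) + \varepsilon$$

with $f_a, f_e$ drawn from a fixed transform catalogue (identity, square
root, square, cube, natural log, reciprocal; additionally $\ln(100 -
\mathrm{age})$ for age). Continuous covariates are centred at the cohort mean
of the *transformed* covariate, so the intercept is the reference-population
mean and a fitted model can be shipped as a self-contained correction
formula. Sex enters as one binary contrast with female as the reference —
an arbitrary but fixed coding recorded in every output.

Enumerating predictors × transforms gives 98 candidate models per score with
the six-transform set, or 112 when $\ln(100-\mathrm{age})$ is included
(`enumerate_models()`). A count of 111 sometimes quoted for this design is
not reproducible from any combinatorics of the catalogue (98 without the
extra age transform; 112 with it, null model included); the package supports
both defensible sets and defaults to 98.

**Selection.** Candidates are compared by the Gaussian maximum-likelihood
BIC, $-2\log L + k \ln n$, with $k$ counting intercept, slopes *and* the
residual variance — the convention of `stats::BIC()`, against which the
implementation is tested. The written selection rule ("at least 2 points
lower, else prefer fewer parameters") does not resolve multi-way ties, so it
is operationalised deterministically: the candidate set is every fit within
2 BIC points of the minimum; the winner has the fewest parameters, ties
broken by lower BIC, then by canonical enumeration order.

**Correction scores.** A selected model yields the additive correction
$-\sum_j \beta_j (f_j(x_j) - \bar f_j)$; corrected = raw + correction. The
polarity follows the published grids: a participant whose demographics
predict slow performance has the expected excess time *subtracted* (the
worst printed cell for T1 is −14.12 s at age 85–90, education 0–4), and a
young, highly educated participant gets time added back. Band-midpoint grids
evaluate the correction at $(lo+hi)/2$ of the printed bands (ages
20–24 → 22, …, 85–90 → 87.5; education 0–4 → 2, 5–8 → 6.5, 9–13 → 11,
14–19 → 16.5); these midpoints reproduce every verified printed cell to
2 decimals. Display rounding is half-away-from-zero, matching the printed
tables; full precision is kept internally.

**The frozen published norms.** `load_published_norms()` ships the twelve
published correction formulas digit-for-digit, the printed grids, and the
printed tolerance limits / ES cut-offs. For eight scores the exact formula
regenerates every printed grid cell at 2 d.p. (T1, T2, T3, E2, E3, T4−T2,
T3−T1, E4−E2 — the package tests all 396 cells). For T4, E4, T4−T3 and E4−E3
the published formula and grid disagree (most starkly T4−T3, whose printed
age coefficient of 7.15 s/year is incompatible with the grid's ≈0.43 s/year
slope); the package does not guess the intended coefficients. These scores
carry `consistent = FALSE`, scoring uses nearest-band grid lookup for them,
and the as-published formula remains available for inspection. Notably, all
four inconsistent grids are *exactly* linear in their selected model form
(ln-education + age³ for T4 and E4; √education + age for T4−T3;
1/education + age³ for E4−E3), which is how the synthetic generator obtains
coefficients for them (below).

## Tolerance limits and Equivalent Scores

Adjusted scores are ranked worst-to-best, abstracting polarity (times and
errors sort descending). With $X \sim \mathrm{Binomial}(n, 0.05)$ counting
sample values in the population's worst-5% tail, the **outer tolerance
limit** is the sample value at the largest rank $r$ with
$P(X \ge r) \ge 0.95$ — guaranteeing with 95% confidence that at most 5% of
the population scores worse — and the **inner limit** at the smallest rank
with $P(X \le r-1) \ge 0.95$. At coverage 0.95/confidence 0.95 an outer
limit first exists at $n = 59$ ($0.95^{59} \le 0.05$). Confidence 0.95 is
used for both limits, the standard in the Equivalent-Scores literature (the
source procedure states only the 5% population fractions).

ES cut-offs by rank subdivision: worse than the OTL → ES 0; at or better
than the sample median → ES 4; the ranks strictly between the OTL rank and
the median rank form three contiguous blocks of equal count. When the block
count is not divisible by 3 (the procedure leaves this unstated) the surplus
ranks are given to the worse blocks, deterministically. Cut-offs take the
sample value at the boundary rank; assignment is strict on the worse side
and inclusive on the better side, so ties fall in the better class, and
collapsed classes (adjacent equal cut-offs, which occur in the published T1
row) are skipped. The ITL is computed and reported but plays no role in ES
assignment — only the OTL anchors ES 0; the published tables list the ITL
alongside the cut-offs without an assignment rule, and the package follows
that.

Two properties define correctness here and are tested: the five classes
partition the real line for arbitrary bands, and over 1 000 simulated
normative samples of $n = 452$ the OTL violates its 5%-coverage bound in at
most ~5% of samples. Note the outer limit is *deliberately* biased beyond
the population 95th percentile (at $n = 10\,000$ it sits near the 96.4th
percentile); that bias is the price of the confidence guarantee, not an
implementation error.

## Clinical validation

ROC analyses use demographically corrected scores, patients as the positive
class, and "above the cut-point indicates pathology" with strict `>`. AUC is
the rank statistic $P(\mathrm{pos} > \mathrm{neg}) + \tfrac12
P(\mathrm{pos} = \mathrm{neg})$; the Youden index is maximised over the
finite candidate set of midpoints between adjacent distinct pooled values
plus $\pm\infty$, so degenerate contrasts resolve at a boundary without
error. Youden ties break toward higher specificity (a normative context
favours specificity), then toward the lower cut-point. Accuracy, prevalence,
PPV and NPV follow the standard definitions, with zero-denominator ratios
reported as missing rather than zero.

## Power analysis

`required_n_f2()` solves the noncentral-F power equation for the denominator
df $v$ at noncentrality $\lambda = f^2(u + v + 1)$. Two sample-size readings
coexist in practice: the design-implied total $u + v + 1$, and the bare $v$
that solver output displays and published power analyses often quote. At
$u = 3$, $f^2 = 0.03$, $\alpha = 0.05$, power 0.80 the solve gives
$v = 363.35$, hence suggested $n = 363$ by the quoted-$v$ convention and
total $n = 367$; both are returned (`n_suggested`, `n_total`) so the
convention is always explicit.

## What the synthetic generator emulates — and what it does not

The generator is the package's study-conditions fixture, not a tuning dial.
Healthy demographics reproduce the reference stratum table *exactly* (452
participants; 252 female/200 male; integer ages uniform within 5-year bands,
integer education uniform within bands with a floor of 1 year so log terms
are defined). Times are linear predictors in the published model forms plus
Gaussian noise truncated below at 0.5 s; intercepts are the printed healthy
means (e.g. T4 61.252 s), demographic coefficients are the published
formula coefficients (consistent scores) or the grid back-fits (flagged
scores), and residual SDs follow from the printed total SDs and model $R^2$
via $\sigma = SD\sqrt{1 - R^2}$ (e.g. T4: $20.781\sqrt{0.43} = 13.6$ s).
Errors are beta-binomial over the 50 items (E1 constantly zero; dispersion
set so total SDs match the printed descriptives), which respects the item
ceiling. E2 is the one deliberate departure: its published age coefficient
implies ±19-error demographic shifts, impossible for a bounded count with
mean 0.126 and SD 0.442, so the generator uses an attenuated age³ effect of
the E3 magnitude. AD/MCI cohorts are additive shifts on tasks 3–4 only
(AD: +35 s on T4, +8 errors on E4; MCI: +15 s, +3), with tasks 1–2 missing,
mirroring the retrospective patient records.

Passing tests on these cohorts therefore demonstrate *procedural*
correctness — exact stratification, transform recovery at realistic effect
sizes, calibrated tolerance limits, separable clinical groups — not fidelity
to any real population: real Stroop times are right-skewed rather than
truncated-Gaussian, errors and times correlate within person, and regional,
linguistic and cohort effects are outside the generating model. Published
cut-offs should always come from `load_published_norms()`, not from
refitting synthetic data.

## Numerical choices and degenerate inputs

* OLS via QR; rank-deficient designs error naming the collinear terms;
  transform domain violations (ln/reciprocal of education 0, age ≥ 100 under
  ln(100 − age)) error naming the transform.
* BIC requires $n > k$; fits on fewer observations are rejected.
* Constant adjusted-score samples yield degenerate bands (all cut-offs
  equal, flagged); every value then maps to ES 4 unless strictly worse.
* Missing raw scores propagate to missing indices and missing ES — never
  imputed, matching how partial patient panels are analysed.
* The zero floor on difference indices applies at the raw-index stage,
  before model fitting, since the recode is defined on the dependent
  variable.

## Problem sizes in the test suite

The suite fixes its own scales: transform-recovery uses 50 replicate cohorts
of $n \approx 2\,000$ (the reference strata scaled ×4.42) for T4 and T3,
asserting ≥80% recovery of the generating ln-education + age³ pair and
coefficient bias within 3 Monte-Carlo SEs; tolerance calibration uses 1 000
samples of $n = 452$ plus an exhaustive rank scan for $n = 59\ldots500$;
oracle-equivalence checks (normal equations, brute-force AUC/Youden/Holm)
run on samples ≤ 50 where exhaustive enumeration is exact. The full suite
runs in well under a minute on one core.

## Known limitations

* The four inconsistent published formulas are preserved, not repaired;
  grid lookup quantises those corrections to band resolution.
* Norms extrapolate poorly outside ages 20–90 and education 1–19; grid
  lookup clamps to the nearest band by design.
* The repeated-measures machinery is intentionally minimal (paired d, Holm,
  Greenhouse–Geisser ε); no full repeated-measures ANOVA or binomial GLM is
  provided.
* Confidence intervals for AUC and alternatives to the Youden criterion are
  out of scope.
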