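---
title: "The Cohen MRI score for hamstring injury: model, rubric and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Cohen MRI score for hamstring injury: model, rubric and synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hamscore)
```

## The problem

Acute hamstring strains are among the most frequent injuries in running
sports, and the clinical question that matters most — *how long until the
athlete can return to sport (RTS)?* — is notoriously hard to answer from a
single early MRI. The Cohen scoring system is one attempt: a radiologist
reads a handful of structured findings off the scan (which muscles are
involved, where along the muscle, how much of the cross-section, how far the
signal extends craniocaudally, whether the insertion is involved, whether
the tendon has retracted), adds the athlete's age, and converts each finding
into 0–3 points via fixed bins. The sum is an ordinal severity score whose
claimed use is prognosis: higher score, longer time away.

`hamscore` implements that rubric as *data*, the standard statistical
evaluation of the score against RTS duration, and a calibrated synthetic
cohort generator so the whole pipeline can be exercised and tested without
access to per-subject clinical data (which, for the cohort this package
emulates — 110 MRI-positive hamstring injuries in adult male professional
footballers — was never published).

## The rubric

Each of the seven components maps its value into an ordered set of bins:

| points | age (y) | muscles (n) | location | insertion | transverse (%) | retraction (cm) | sagittal (cm) |
|---|---|---|---|---|---|---|---|
| 0 | — | 0 | — | no | 0–<25 | 0 | 0 |
| 1 | ≤25 | 1 | proximal | — | 25–<50 | >0–<2 | >0–<5 |
| 2 | 26–31 | 2 | middle | yes | 50–<75 | ≥2 | 5–<10 |
| 3 | ≥32 | 3 | distal | — | ≥75 | — | ≥10 |

Conventions this package commits to (the printed sources are ambiguous in
places):

* **Bin boundaries** are lower-inclusive half-open intervals (`[25, 50)`),
  following the rubric's own `25–<50` rendering; integer renderings such as
  `25–49%` are read as the same intervals.
* **Zero bins** for retraction and sagittal extent are the degenerate point
  `[0, 0]`: absence scores 0, and *any* positive measurement scores at least
  1. Consequently a valid MRI-positive record (which must have positive
  sagittal extent) can never take the sagittal 0 bin.
* **Ages** are floored to whole years before binning; ages outside the study
  eligibility window 18–50 are rejected, since the rubric is undefined there.
* **Multi-muscle injuries** are scored from the primary (most severely
  injured) muscle's location and size measurements only, matching how
  cohort reports give a single location and size per injury.
* **MRI-negative records** are scoreable — they keep the age component only,
  so the lowest achievable total is 1 — but are excluded from summaries and
  evaluation, as in practice.

The rubric lives in a JSON config
(`system.file("extdata", "rubric_default.json", package = "hamscore")`), so
variant parsings can be swapped in without touching the scorer; the shipped
`rubric_absolute_pct.json` implements the alternative *absolute* reading of
the cross-sectional percentage (nearest of 0/25/50/≥75%), which the
original description of the system arguably intended.

### Structural bounds by enumeration, not by assertion

The literature disagrees about this score's floor and ceiling (a claimed
minimum of 2 and maximum of 16 versus an observed range of 4–12 under the
parsing above). `enumerate_score_range()` settles the question for whatever
rubric is loaded by brute force: one representative value per bin per
component, subject to the record invariants, every combination scored:

```{r}
enumerate_score_range(default_rubric(), mri_positive = FALSE)[1:2]
enumerate_score_range(default_rubric(), mri_positive = TRUE)[1:2]
```

Under the default parsing an MRI-positive injury is forced to at least 1
point each from age, muscle count, location and sagittal extent — minimum 4,
consistent with the observed range — while the grid's column maxima sum
to 19. Neither 2 nor 16 is reachable under this parsing, and the package
deliberately reports the enumerated bounds of the loaded rubric rather than
hard-coding any published claim.

## The evaluation

`evaluate_cohort()` reproduces the standard validation analysis for a
prognostic severity score against RTS days:

* **Normality** of both variables by the one-sample Kolmogorov–Smirnov test
  with the **Lilliefors correction** (parameters estimated from the data;
  p-value by the Dallal–Wilkinson 1986 approximation). The uncorrected KS p
  would be badly conservative here.
* **Correlation**: Pearson's r on raw values *and* Spearman's rho as Pearson
  on mid-ranks (tie-corrected; ties are guaranteed with an integer score),
  reported side by side under unambiguous names because published tables
  sometimes label one as the other. Variance explained is `100·r²` percent.
* **Dichotomization** at a configurable threshold (default 10, the
  conventional cut): group sizes, means, medians, SDs; the mean difference
  (high-score minus low-score group) with a **Welch** 95% CI and two-sided p
  (robust to the very unequal group sizes a cut at 10 produces); and
  **Cohen's d** with the pooled SD — the standard formulation for a
  two-group standardized mean difference; the package documents this choice
  because "effect size" is often reported without naming a formula.

Numerical edge cases are defined, not silent: zero variance in either
variable makes correlation a classed error; a zero pooled SD makes d `NA`
with a classed warning (never an infinity); an empty group suppresses the
comparison but still returns the partition.

## The synthetic cohort

`generate_cohort()` emulates the cohort the analysis was designed for. Its
defaults are the published facts, fixed once:

* **Marginals** are the published category counts normalized: muscle count
  89/21/1, primary muscle 89/17/3/1, location 21/46/44, transverse bin
  76/18/10/5, sagittal bin 16/37/57. Components are sampled
  **independently**, because only marginals were published; the per-variable
  denominators (111, 110, 111, 109, 110) are intentionally used as printed.
* **Age**: `18 + Binomial(21, 8/21)` — support exactly the published range
  18–39, mean exactly the published average 26, unimodal. A discrete uniform
  on 18–39 was considered and rejected: its mean is 28.5, contradicting the
  published average. (With this age model the synthetic mean total score
  comes out near 7.9, the published value — a soft consequence, not a
  calibration target.)
* **Insertion/retraction** are fixed at no/0 cm: complete ruptures were an
  exclusion criterion and none were observed.
* **RTS** follows `RTS = α + β·score + ε`, `ε ~ N(0, σ²)`, floored at 1 day
  and rounded to whole days. `calibrate_rts_model()` solves the moment
  conditions exactly: `β = r·σ_RTS/σ_score`, `σ = σ_RTS·√(1−r²)`,
  `α = μ_RTS − β·μ_score`, with targets μ = 22.65 d, σ = 11.03 d, r = 0.205.

**Which score moments feed the calibration?** The generated cohort's own
(`mean`, `sd` of the generated totals), not the published 7.9/1.71. The
synthetic score SD under independent marginals is ≈1.53 — real components
are correlated, so the published SD is larger — and plugging 1.71 into β
would systematically attenuate the realized correlation to ≈0.18. Using the
cohort's own moments makes the configured `target_r` the *true* correlation
of the generative model, which is what makes parameter-recovery testing
(ρ* ∈ {0, 0.2, 0.8} recovered within ±0.03 at n = 10,000) meaningful.
Explicit `(α, β, σ)` can still be supplied via `rts_model = list(type =
"linear", ...)`.

The floor-and-round step biases the RTS mean upward by ≈0.1 day at the
default calibration (measured empirically at large n, asserted < 0.5 day);
it is not analytically corrected. A right-skewed `"lognormal"` noise variant
is provided because the published range (1–66, mean 22.65, SD 11.03) and the
violated normality test suggest skew, but no published moments pin its
shape, so it is exploratory and the Gaussian model stays the default.

**What a green test does and does not establish.** The generator reproduces
marginal frequencies and second-order moments (means, SDs, one correlation).
It does not reproduce the joint dependence among MRI variables, the exact
p-values, the observed score range 4–12 as a data property, the group
difference of 9.8 days, or the effect size 0.85 — those depend on the
unpublished per-subject data and are deliberately *not* asserted anywhere.
A hook for a joint table (`marginals` replacement plus explicit RTS
coefficients) exists if such data ever surface.

## Seeding and determinism

One root seed drives per-variable sub-streams (derived once via a seeded
`sample.int`), so editing one part of the config does not shift the random
streams of unrelated variables. Identical config ⇒ bit-identical cohort;
the pipeline adds no randomness of its own, so a fixed input yields a
byte-identical report bundle.

## Known limitations

* Independence of MRI components is a modelling convenience; real injuries
  plausibly couple size, location and muscle count, which is why the
  synthetic score SD (≈1.53) undershoots the published 1.71.
* The Lilliefors p-value is an approximation (as in every standard
  implementation); the statistic itself is exact.
* Percent rendering is half-up to one decimal to match clinical reporting;
  one published percentage (the sagittal `1–5 cm` bin's 14.6%) matches no
  count/denominator combination and is not asserted.
* Quartiles use linear interpolation (type 7); published IQRs computed with
  SPSS-style hinges can differ by up to one unit at these sample sizes, so
  IQR values are reported but never asserted against published ones.
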