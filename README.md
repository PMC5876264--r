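# hamscore

Scoring and prognostic evaluation of the **Cohen MRI score** for acute
hamstring muscle injury, with a calibrated synthetic-cohort generator.

## Who this is for

Sports-medicine and biostatistics researchers who want to (a) compute the
Cohen MRI severity score from structured radiology readings, (b) run the
standard validation analysis of such a score against return-to-sport (RTS)
duration, or (c) simulate realistic cohorts for methods work when
per-subject clinical data are unavailable.

## The score and the analysis

The score is additive over seven components — athlete age, number of
hamstring muscles involved, injury location (proximal/middle/distal),
insertional involvement, transverse cross-sectional percentage, tendon
retraction (cm), and craniocaudal sagittal extent (cm) — each binned to 0–3
points (component maxima 3/3/3/2/3/2/3, grid maximum 19). The evaluation
against RTS days comprises Lilliefors-corrected Kolmogorov–Smirnov
normality tests, Pearson's *r* and tie-corrected Spearman's ρ with the
variance explained 100·*r*², and a dichotomized comparison at score ≥ 10:
mean difference with Welch 95% CI and Cohen's *d* = (μ₁−μ₂)/s_pooled.

The synthetic generator samples the MRI variables from the cohort's
published marginal frequencies and draws RTS from a linear-Gaussian model
RTS = α + β·score + ε moment-calibrated (`calibrate_rts_model()`) to the
published targets: mean 22.65 d, SD 11.03 d, Pearson r = 0.205. See the
methods vignette (`vignettes/cohen-mri-score.Rmd`) for every modelling
choice.

## Worked example

```r
library(hamscore)

score_injury(age = 24, n_muscles = 1, location = "middle",
             transverse_pct = 30, sagittal_extent_cm = 12)$total
#> [1] 8

enumerate_score_range(default_rubric(), mri_positive = TRUE)[1:2]
#> $min_total: 4     $max_total: 19

co <- generate_cohort(n = 110, seed = 42)   # synthetic cohort
evaluate_cohort(co)
#> Evaluation of 110 scored injuries
#>   Pearson r = 0.167 (p = 0.080); Spearman rho = 0.174 (p = 0.070)
#>   Variance explained: 2.8%
#>   Score < 10: n = 98, mean RTS 22.8 d; score >= 10: n = 12, mean RTS 23.0 d
#>   Difference 0.2 d (95% CI -8.8 to 9.3), Cohen's d = 0.02
```

Reading: at n = 110 the configured population correlation (0.205) explains
~4% of RTS variance, so single-cohort estimates scatter widely — here the
sample gives r = 0.167 (2.8%), and the score ≥ 10 group (n = 12) happens to
show almost no mean RTS advantage. That instability is precisely the
clinical finding the evaluation module is built to expose.

A full report bundle (scored records, summary tables, evaluation JSON,
plot-data CSVs for the scatter + fit, group dot plot and per-muscle-count
means):

```r
run_pipeline(co, out_dir = "report")
```

or from the shell, via the bundled CLI:

```sh
Rscript inst/cli/hamscore simulate --n 110 --seed 42 --out records.csv
Rscript inst/cli/hamscore pipeline --input records.csv --threshold 10 --out report/
```

Swap in an alternative rubric parsing with
`--rubric inst/extdata/rubric_absolute_pct.json` (or `rubric =` in R).

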