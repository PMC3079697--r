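# actiq

Measurement properties of physical-activity questionnaires against
accelerometry.

Clinical studies — for instance in cancer patients during or after
chemotherapy — often have to measure physical activity (PA) with short
7-day recall questionnaires. Before such an instrument can track a
patient's activity over time, two questions must be answered: does it give
the same answer when nothing has changed (test–retest reliability), and
does it measure actual movement (construct validity against an
accelerometer)? `actiq` implements that entire evaluation pipeline for two
widely used instruments:

* **AQuAA** (Activity Questionnaire for Adults and Adolescents): activity
  entries with frequency, duration and perceived intensity, scored into a
  total score in MET·min/week (activities ≥ 2 MET) and weekly minutes of
  sedentary (< 2 MET), light (2–4), moderate (4–6.5) and vigorous (≥ 6.5)
  activity;
* **PASE** (Physical Activity Scale for the Elderly): categorical items
  scored as a weighted sum `Σ wⱼ·hⱼ` of hours/week, plus total-PA and
  sedentary minutes.

Alongside: ActiGraph-style 15-s epoch processing (counts/min, the 60-min
consecutive-zeros non-wear rule, Freedson cut-points 100 / 1952 / 5725
counts/min, the 600-min valid-day and 5-of-7-day inclusion rules), the
reliability statistics

```
ICC  = (MSB − MSW) / (MSB + MSW)        one-way random effects, k = 2
SEM  = √MSW
SDD95 = 1.96 · √2 · SEM
steps = round(range95 / SDD95)          range95 = P97.5 − P2.5
```

with exact F confidence intervals, and construct-validity statistics
(Spearman rₛ with t or permutation p-values, two-way consistency agreement
ICCs, ACSM 150-min guideline compliance). A calibrated synthetic-cohort
generator (`simulate_cohort()`) with known variance components and known
questionnaire–accelerometer coupling makes every stage testable end to
end; see the methods vignette (`vignettes/measurement-properties.Rmd`)
for the model and its calibration.

## Worked example

Simulate a 50-patient validation cohort, score both questionnaires at both
administrations, summarise the accelerometer streams, and build the
reliability and validity tables:

```r
library(actiq)

cfg     <- cohort_config(n_subjects = 50)   # calibrated defaults
cohort  <- simulate_cohort(cfg, seed = 2026)
scores  <- score_questionnaires(cohort)
rel     <- reliability_table(scores)
rel[, c("score", "icc", "icc_lower", "icc_upper", "sem", "sdd95", "ratio", "steps")]
#>             score   icc icc_lower icc_upper    sem  sdd95 ratio steps
#> 1     aquaa_light 0.556     0.332     0.721 136.21  377.5 0.502     2
#> 2      aquaa_mvpa 0.633     0.434     0.773  48.56  134.6 0.491     2
#> 3     aquaa_score 0.612     0.406     0.759 649.22 1799.6 0.474     2
#> 4 aquaa_sedentary 0.786     0.653     0.873 135.79  376.4 0.313     3
#> 5  aquaa_total_pa 0.564     0.343     0.727 138.74  384.6 0.480     2
#> 6      pase_score 0.841     0.737     0.906   5.61   15.6 0.297     3
#> 7  pase_sedentary 0.646     0.452     0.782  68.41  189.6 0.560     2
#> 8   pase_total_pa 0.845     0.743     0.909 114.86  318.4 0.292     3
```

Read a row as: the PASE sum score has good-to-excellent repeatability
(ICC 0.84, 95% CI 0.74–0.91); a patient must change by more than
SDD95 ≈ 16 points before the change outruns measurement error, and the
scale can distinguish about 3 such steps across its observed range. ICCs
near 0.56–0.63 for the AQuAA rows rate only fair-to-good, matching the
general finding that activity recall over a week is noisy.

Construct validity against the simulated accelerometer:

```r
summaries <- summarize_cohort(cohort$epochs)
val <- validity_table(scores, summaries)
val[val$instrument != "actigraph",
    c("score", "rho", "p_value", "icc", "n_included")]
#>              score    rho p_value    icc n_included
#> 6      aquaa_score  0.182    0.21     NA         50
#> 7   aquaa_total_pa     NA      NA -0.057         50
#> 9       aquaa_mvpa     NA      NA  0.252         50
#> 10 aquaa_sedentary     NA      NA  0.474         50
#> 11      pase_score -0.027    0.85     NA         50
#> 13  pase_sedentary     NA      NA  0.158         50
```

Total scores correlate only weakly with measured counts/min (rₛ ≈ 0.18 and
−0.03 here) and the per-band agreement ICCs are poor to fair — the
well-documented gap between self-reported and measured activity, which the
generator reproduces by design. `run_pipeline(out_dir, seed = ...)` runs
the whole chain and writes the scores, summaries, both tables and a JSON
manifest (seed + configuration hash) so any run can be replayed exactly.

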