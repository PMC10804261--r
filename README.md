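# esmaff — affect dynamics from experience sampling data

`esmaff` analyses **emotional intensity, variability, and instability** in
intensive longitudinal data collected by the Experience Sampling Method
(ESM): participants are prompted 8 times a day for 7 consecutive days
(two-hour slots, 08–10 … 22–24) and rate seven momentary emotions (happy,
sad, tired, relaxed, nervous, calm, full of energy) on a 0–100 scale. The
package targets the three-group design used in severe-mental-illness
research — residential patients with a schizophrenia spectrum disorder,
outpatients, and healthy controls — and ships a synthetic-data generator
with that design's published descriptive statistics as defaults, so the
whole pipeline is testable without access to restricted raw data.

It is written for biostatisticians and psychiatric-epidemiology groups who
need a reproducible path from raw prompt-level CSVs (or a simulated
cohort) to the standard result tables of an ESM affect-dynamics paper.

## The statistics at its core

Composites per answered prompt: positive = mean(happy, relaxed, calm,
full of energy); negative = mean(sad, tired, nervous). Subjects answering
< 30% of their scheduled prompts are excluded (17/56 is the smallest
retained count). For each group and polarity:

- **Between-person variability** — population variance of subject mean
  ratings: `σ²_B = Σᵢ (X̄ᵢ − X̄)² / n`.
- **Within-person daily / weekly variability** — unit-level means `X_ij`
  (subject i in two-hour slot j, or on weekday j) deviate from the
  subject's grand mean `X̄ᵢ`; squared deviations are pooled over subjects
  and divided by the total number of observed (subject, unit) cells.
- **Instability** — mean absolute successive difference `|x_{t+1} − x_t|`
  over same-day successive answered prompts (square-rooted successive
  squared differences; the overnight pair is excluded).
- **95% CIs** — percentile bootstrap resampling *subjects* (B = 2000 by
  default), respecting within-person dependence.

Downstream inference mirrors the field's conventions: KS-gated ANOVA /
Kruskal–Wallis group comparisons with Bonferroni post-hocs, Spearman
correlation matrices against clinician-rated totals (BPRS, BNSS, SLOF),
Gaussian GLM backward elimination for predictors of per-subject
variability/instability, and linear + quadratic time-trend models over
time-of-day (slot 1–8) and weekday (1 = Monday) with a subject random
intercept estimated by maximum likelihood (`lme4`).

## Worked example

```r
library(esmaff)

cfg <- default_paper_config()          # 57/46/112 subjects, p_resp = 0.636
ds  <- generate_dataset(cfg, seed = 1)
ds
#> <esm_dataset> 215 subjects (residential=57, outpatient=46, control=112),
#>   12040 scheduled prompts, 7535 answered (62.6%)

cf    <- compliance_filter(ds, threshold = 0.30)
panel <- compute_composites(cf$dataset)

ctrl <- panel[panel$group == "control", ]
between_person_variance(subject_means(ctrl, "positive"))
#> [1] 141.4336        # generator's tau^2 for this cell is 11.9^2 = 141.6

bootstrap_ci(ctrl, "between_person", "positive", B = 2000, seed = 2)
#> <esm_estimate> between_person (positive): 141.43 [95% CI 104.77; 178.27],
#>   n=112, B=2000

instability(ctrl, "positive")
#> [1] 9.826728        # mean |successive same-day change|, 0-100 scale
```

`9.83` says that a healthy control's positive-emotion rating moves by
about ten points (on 0–100) between consecutive answered prompts within a
day; `141.4` is the between-person variance of subject means, i.e. an SD
of ~12 points separating people in their habitual positive affect.

The whole pipeline, writing the five result tables plus a manifest:

```r
run_pipeline(run_config(sim_config = cfg, seed = 1, out_dir = "out"))
```

A command-line wrapper lives in `inst/cli/esmaff`
(`esmaff simulate | validate | qc | composites | dynamics | run`); see
`?esmaff_cli`.

## Scope notes

The generator emulates group means/SDs, response rate, anti-correlated
positive/negative affect, and control-only weekly/diurnal trends; it does
not simulate response-time dynamics, clustered nonresponse (available as
a config extension), or activity/social-context items. See the methods
vignette (`vignettes/affect-dynamics.Rmd`) for model assumptions, design
decisions, and known limitations — including why time-of-day is coded as
slot index and which acceptance check the stated synthetic world cannot
meet.
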