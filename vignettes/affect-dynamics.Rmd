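---
title: "Methods: emotion dynamics from experience sampling data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emotion dynamics from experience sampling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(esmaff)
```

## The design and data model

`esmaff` analyses momentary emotion ratings from an experience sampling
(ESM) week: 8 prompts per day in fixed two-hour windows (08–10 … 22–24)
for 7 consecutive days, so a fully scheduled subject has 56 prompts. Each
answered prompt rates seven emotions on 0–100; unanswered prompts are kept
as rows with an `answered = FALSE` flag and empty ratings, and nothing is
ever imputed — every downstream statistic uses answered prompts only.

Two storage decisions matter for interpretation:

* **Slots, not timestamps.** Prompts are semi-randomized within their
  two-hour window in the field, but no analysis here uses sub-slot timing,
  so only the 1-based slot index is stored.
* **`day_index` and `weekday` are both kept.** Monitoring can start on any
  weekday; day-of-week analyses use `weekday` (1 = Monday), while
  within-day ordering uses `day_index` + `slot_index`.

Composites per answered prompt: positive = mean(happy, relaxed, calm, full
of energy); negative = mean(sad, tired, nervous). The instrument displays
seven items; "quiet" and "calm" are the same item, named `calm`
throughout. Subjects answering less than 30% of their scheduled prompts
are excluded; the comparison is non-strict (≥), so 17 of 56 — about
30.4% — is the smallest retained count. The denominator is the subject's
actual scheduled rows rather than a hard-coded 56, which is the only
choice that handles partial-week participants; for complete schedules the
two coincide.

## The four dynamics statistics

For a group of $n$ subjects and one polarity, with $\bar X_i$ the mean of
subject $i$'s answered composites and $\bar X$ the group mean of those
means:

$$\text{between-person variance} = \frac{1}{n}\sum_i (\bar X_i - \bar X)^2,$$

a *population* variance (divisor $n$), because the definition used in this
literature is the plain "average squared difference from the mean" of the
subject means.

For within-person variability, let $X_{ij}$ be subject $i$'s mean in unit
$j$ (two-hour slot for *daily*, weekday for *weekly*) and $\bar X_i$ the
mean of subject $i$'s unit-level means. The textbook denominator $nm$
(units × subjects) is only defined for balanced data; with missed prompts
different subjects observe different unit counts. The one reading that is
well defined for unbalanced data, and reduces to $nm$ when balanced, is

$$\text{within-person variance} =
  \frac{\sum_i \sum_j (X_{ij} - \bar X_i)^2}{\#\{(i,j)\ \text{observed}\}}.$$

Subjects with fewer than two observed units carry no information about
within-person spread and are dropped from this metric with a warning.
$\bar X_i$ here is the mean of the unit-level means (paired with $X_{ij}$),
not the raw-prompt mean; the two differ when unit sizes are unequal, and
the unit-mean version keeps the numerator a pure sum of deviations around
the quantity it is compared to.

**Instability** is the mean absolute successive difference: answered
prompts are ordered by slot within each day, successive same-day pairs
contribute $\sqrt{(x_{t+1}-x_t)^2} = |x_{t+1}-x_t|$, and the estimate
pools all pairs of all subjects. The square root is applied *per pair*
(mean absolute successive difference), not after averaging (which would be
the RMSSD) — the stated computation order is squared differences first,
then the square-root transform. Overnight pairs (last prompt of one day to
first of the next) are excluded. Pooling pairs across subjects matches the
pooled-cells convention of the variance metrics; a
`per_subject_first = TRUE` flag averages subject-level means instead.

**Confidence intervals.** The source tables print 95% CIs without naming a
method, so CI agreement is explicitly *not* a target. The package uses a
percentile bootstrap resampling subjects — the exchangeable unit, so
within-person dependence is preserved — with `B = 2000` and a mandatory
seed. Internally the bootstrap aggregates per-subject sufficient
statistics (subject means; per-subject deviation sums and cell counts;
per-subject absolute-difference sums and pair counts), which is
algebraically identical to materializing each resample; the test suite
checks that equivalence against a literal resample-and-recompute oracle.
Degenerate resamples simply yield the degenerate value.

## Inference conventions

* **Group comparisons**: per-group Kolmogorov–Smirnov checks against a
  fitted normal gate one-way ANOVA vs Kruskal–Wallis; Bonferroni post-hocs
  (`p_adj = min(1, p_raw × #pairs)`) run only when the omnibus test is
  significant. Categorical outcomes go through a chi-square test.
* **Clinical correlations**: Spearman, pairwise-complete, emitted for the
  pooled patient sample and each patient subgroup; cells with fewer than 3
  complete pairs are flagged rather than computed.
* **Backward elimination**: "generalized linear models" with an unstated
  family is read as Gaussian/identity on the continuous per-subject
  variability and instability outcomes. Terms are removed one at a time by
  the largest single-term-deletion F-test p ≥ 0.05 (whole factors are
  dropped as units), the trace is recorded, and rank deficiency is an
  error naming the collinear terms. Group is available as a candidate but
  never forced.
* **Time trends**: rating ~ time (linear) and rating ~ time + time²
  (quadratic), each with a subject random intercept estimated by maximum
  likelihood (`lme4`, `REML = FALSE`) so missing prompts are handled by
  likelihood, with a pooled-OLS fallback flag. Time is centered at the
  axis midpoint before squaring to reduce collinearity and the
  coefficients are mapped back to the uncentered scale
  ($\beta_1 = b_1 - 2c\,b_2$, with the delta-method SE). The reported
  "time" row comes from the linear model and "time²" from the quadratic
  model. CIs and p-values are Wald/normal; singular random-intercept fits
  (variance 0) are legitimate and equal OLS.

**Time-of-day is coded as slot index 1–8, not clock hour.** This is a
deliberate deviation from the obvious clock-hour midpoint coding, forced
by magnitude consistency: the published diurnal coefficients (≈1.0 linear,
≈0.11 quadratic) on clock hours 9–23 would imply a ~63-point
morning-to-evening swing on a 0–100 scale whose group mean is ~23 —
impossible — while on a slot axis they imply a ~14-point swing, the same
order as the weekly trend printed beside them (weekday is coded 1–7 in
both cases). One slot unit equals two hours.

## The synthetic world

The generator *states* a world matching the published design; its defaults
are the published descriptive values and are not tuned:

| parameter | value | source/rationale |
|---|---|---|
| group sizes | 57 / 46 / 112 | published sample |
| μ, τ (person-level mean, SD) | e.g. control positive 60.1, 11.9 | published intensity means/SDs mapped directly to the person-mean distribution |
| σ (residual SD) | instability × √π/2, e.g. control positive 8.70 | for iid Gaussian residuals E\|Δ\| = 2σ/√π, so σ reproduces the published instability |
| ρ (pos–neg anti-correlation) | −0.6 | applied to person means and residuals; mirrors the published r ≈ −0.58 qualitatively |
| p_resp | 0.636 | published response rate, independent Bernoulli per prompt |
| trends | controls only: weekday (1.03, 0.13) positive, (−0.75, −0.10) negative; diurnal slots (0.97, 0.11) negative | published control coefficients on the slot/weekday axes; patient groups trendless ("chaotic") |
| item noise | SD 2, clamped to ±1.5, rounded | items only need to round-trip through composite scoring; composites recover the latent within ±2 |

Person means and residuals are Gaussian truncated into [0, 100] (the
instrument's scale is real; values cannot leave it). Trend surfaces are
mean-centered over the full grid before injection, so they change neither
the group mean nor the polynomial coefficients a trend model recovers.
Each subject's week starts on a uniformly drawn weekday (recruitment is
rolling), which decorrelates `day_index` from `weekday`. Patients receive
clinical covariates from truncated Gaussians at the published group
means/SDs, tied together by a latent severity factor; missingness is
ignorable by construction, matching the pipeline's complete-case
treatment. Clustered nonresponse and response-time dynamics are *not*
simulated, so green tests say nothing about informative missingness.

Where the generator's exactness example (a fully degenerate configuration
producing a constant composite) conflicts with item-level noise, the noise
SD is a config field: `item_sd = 0` gives exact constants, the default 2
gives ±2 recovery.

## What the acceptance checks establish — and one honest failure

The headline variance/correlation/trend tables of the source study depend
on restricted raw data and are not desk-reproducible; acceptance is
therefore (a) the arithmetically self-contained printed numbers
(compliance minimum 17/56; 13,496 scheduled prompts for 241 participants;
63.6% response rate; 2.5% and 5.3% flow percentages), (b) exact oracle
equivalence of all four dynamics metrics against brute-force
re-implementations on 1,000 random micro-datasets, and (c) calibration
properties of the simulation (trend-coefficient recovery, null retention
rate of backward elimination ≈ 5%, uniform null p-values).

One stated check fails, and is left failing: bootstrap CIs for
between-person variance cover τ² in ≥ 90% of seeds in only 2 of 6
group × polarity cells (measured pooled rate 84%). The cause is the
world's own geometry, not the estimators (which are oracle-exact):
truncation to [0, 100] shrinks the *realized* between-person variance
9–14% below the nominal τ² wherever the group mean sits within about 2τ of
a scale bound — all negative-emotion cells, and the residential positive
cell at the ceiling — and the percentile bootstrap for a variance
additionally under-covers at n ≈ 46–57. The cell essentially free of
truncation distortion (control positive, n = 112) covers at 92/100.
Widening the band, shrinking τ, or moving the means would make the check
pass and the world dishonest; the discrepancy is documented instead.

## Numerical and degenerate-input choices

* Bootstrap percentile endpoints use R's default quantile type 7; seeds
  are mandatory everywhere randomness exists, and per-cell seeds in the
  full dynamics table are derived deterministically from the master seed.
* Subjects with no answered prompts are excluded from subject means with a
  warning; groups below the minimum size for a metric raise errors rather
  than returning NaN.
* The compliance denominator for a subject with zero scheduled rows is
  undefined; such subjects are excluded and flagged `"no schedule"`.
* Validation is total: `validate_dataset()` reports every violation it can
  find on any structurally parseable input and never mutates or raises.

## Known limitations

* Table-level numeric agreement with the source study's variance and
  correlation tables is out of reach by design (restricted data) and is
  not claimed.
* The published SDs conflate between-person spread with sampling noise;
  mapping them directly to τ is an approximation the generator documents
  rather than corrects — it is also one root of the red coverage check
  above.
* Instability here is the unweighted mean absolute successive difference;
  time-weighted MSSD variants and multilevel location-scale models are out
  of scope.
* The random-intercept trend model ignores serial correlation within days;
  with strong autocorrelation its Wald p-values are mildly anti-
  conservative (visible as ~8% null rejection at the 5% level in the
  calibration suite).
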