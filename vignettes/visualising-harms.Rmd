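---
title: "Methods: visualising harm outcomes in randomised controlled trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: visualising harm outcomes in randomised controlled trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4.5)
library(harmvis)
```

Harm (adverse-event) data from randomised controlled trials are usually
reported as frequency tables, although a small set of well-chosen graphics
communicates the harm profile far better: which events differ between
arms, how severe they are, when they occur, and how laboratory markers
shift under treatment. harmvis implements ten such displays together with
the estimators each one embeds, a decision tree for choosing among them, a
synthetic trial generator, and a command-line interface. This vignette
documents the statistical methods, the conventions and defaults, and the
limits of what the package's tests demonstrate.

## Data model

Everything consumes a `trial_dataset`: a roster (participant, arm,
follow-up days), an adverse-event table (term, body-system group, ordinal
severity, onset day), longitudinal continuous measurements, and per-outcome
normal ranges. Conventions, fixed once and used everywhere:

* **Time** is measured in days since randomisation, with `t = 0` at
  randomisation and censoring at the end of each participant's follow-up.
  An event on the censoring day counts as an event (the standard
  tie-breaking convention: events are processed before censorings).
* **Denominators** are all roster participants in an arm — the roster *is*
  the safety population as supplied. Whether that is the randomised or the
  treated population is the caller's choice, made before the data are
  loaded; the package does not subset.
* **Severity** is an ordered scale, by default mild < moderate < severe,
  configurable to admit five-grade toxicity scales. A participant's
  contribution to severity displays is their *maximum* grade per event: a
  participant with a mild and a moderate occurrence of the same event
  counts once, as moderate.
* **Missing body-system groups** default to `"Other"` rather than being
  dropped, so the group-level displays always conserve events.

Validation is total: a file violating any of these invariants is rejected
with a row-addressed message, and valid files round-trip loss-free through
`read_trial()`/`write_trial()`.

## Estimators behind the binary displays

The dot plot's central panel shows one of four comparative measures. For a
2×2 table with `a/n1` events in the comparator arm and `b/n2` in the
reference arm:

* relative risk `(a/n1)/(b/n2)`, log-scale Wald (Katz) interval with
  `SE = sqrt(1/a − 1/n1 + 1/b − 1/n2)`;
* odds ratio, log-scale Wald with the usual four-term standard error;
* risk difference, identity-scale Wald;
* incidence rate ratio `(e1/t1)/(e2/t2)` over exposure time, log-scale
  Wald with `SE = sqrt(1/e1 + 1/e2)`.

All intervals are point ± `z(1 − α/2)` standard errors with α = 0.05 by
default — the familiar 1.96. No interval method is canonical for this
display; the Wald family was chosen because it matches the behaviour of
the established implementations of the dot plot and is what the simple
"1.96 × SE" definition of a 95% interval produces. Score or exact
intervals are out of scope.

**Zero cells.** When exactly one arm records zero events, half an event is
added to each numerator and denominator (`a`, `b`, `n1`, `n2`; counts only
for the rate ratio) and the estimate is flagged `corrected`. So
`effect_estimate(0, 50, 5, 50)` returns `(0.5/50.5)/(5.5/50.5) = 0.5/5.5`.
This continuity correction is simple and common but known to behave poorly
in rare-event meta-analysis; the flag exists so users can report it. When
*both* arms have zero events no estimate is possible: the row is dropped
with a warning and footnoted on the dot plot rather than silently omitted.
The correction applies uniformly across measures when enabled, including
the risk difference (estimable without it, but kept consistent).

**Multiplicity.** Confidence intervals on the dot plot flag potential
signals for further investigation; they are deliberately *not* adjusted
for multiplicity, because treating them as a battery of hypothesis tests
is exactly the misuse the display's framers warn against. The package
performs no hypothesis testing anywhere.

## Time-to-event estimators

`km_estimate()` is the product-limit estimator with Greenwood variance.
Pointwise confidence limits use the complementary log-log transform, which
keeps bands inside [0, 1] without truncation; at steps where the estimate
reaches exactly 0 the band collapses to [0, 0] and the variance is
reported as 0 by convention. The extended at-risk table counts, at each
grid time `t`, the participants still at risk, cumulatively censored, and
cumulatively evented, with events and censorings at exactly `t` included —
so the three columns always sum to the arm size.

`mcf_estimate()` is the non-parametric mean cumulative function for
recurrent events: at each distinct event time the estimate increments by
(events at `t`) / (participants still under observation at `t`). Its
variance is the Lawless–Nadeau robust (sandwich) form, which sums each
participant's accumulated residual `Σ (d_ij − d_j/Y_j)/Y_j` and squares
it, accommodating within-participant correlation; limits are computed on
the log scale so the lower band stays non-negative. The point estimate
coincides with the Nelson–Aalen cumulative hazard of the counting-process
formulation, which is how the test-suite cross-checks it.

`survival_ratio()` compares two arms directly — the within-arm KM bands do
*not* answer the between-arm question — as the ratio (or difference) of
the two KM curves on the union of their event-time grids. Pointwise bands
are percentile intervals over bootstrap resamples of participants drawn
with replacement within each arm; the interval type is a package choice,
documented here, as is the orientation (reference arm in the numerator,
recorded in the output metadata). A seed is mandatory and the output is
bit-reproducible from it. The default 1000 resamples balances Monte-Carlo
noise (≈1% in the 2.5% tail) against runtime. Degenerate resamples are
handled by re-evaluation, not rejection: an all-censored resample gives
S(t) = 1; a resample whose estimate hits zero contributes boundary values
that the percentile quantiles absorb. The ratio is truncated from the grid
once either observed arm's estimate reaches zero. Swapping the arms
reciprocates the estimated curve exactly; the bootstrap bands under a swap
are statistically, not bitwise, reciprocal, because the two arms'
resampling streams are drawn sequentially from the one seed.

**Competing risks are not modelled.** All three estimators treat
censoring as non-informative. When a competing event (death, treatment
discontinuation for another cause) precludes the harm of interest,
event-free-probability estimates are biased and a cumulative-incidence
analysis (Aalen–Johansen, Fine–Gray) should underpin the display instead;
the package deliberately does not offer one.

## Continuous-outcome summaries

`timepoint_summary()` reports, per arm and visit, mean ± SD — the SD of
the raw values, showing population variability, not the standard error of
the mean — or median and IQR. Quantiles use linear interpolation of order
statistics (R's type 7), fixed for reproducibility. Model-based summaries
(e.g. mixed-model means with confidence limits) are accepted by the line
graph as pre-computed rows; fitting repeated-measures models is out of
scope. Summaries are computed at observed visit times only, with no
interpolation between visits.

`kde_estimate()` is a Gaussian kernel density with Silverman's
rule-of-thumb bandwidth `0.9 · min(SD, IQR/1.34) · n^(−1/5)` (falling back
to the SD alone when the IQR is zero), evaluated on a grid spanning the
data ± 3 bandwidths. There is no boundary correction, so densities of
non-negative quantities such as cell counts can extend below zero — a
real limitation of the display that the violin and density plots inherit
and that users should weigh for strictly positive outcomes. A sample with
fewer than two distinct values has no meaningful density; the function
says so and suggests a rug/point display.

`change_scores()` derives per-participant change from baseline
(`visit_time == 0`) to either a fixed visit or the post-baseline maximum.
"Maximum over the trial" means all visits after baseline, including any
after treatment stopped; participants missing the required values are
excluded and itemised rather than silently dropped.

## The figures

Each `plot_*` builder returns a `harm_figure` holding the ggplot object,
the *exact* statistics table it displays (asserted byte-identical in the
tests), and the resolved options, including the per-arm style map. Layout
rules the displays commit to:

* **Dot plot** — three aligned panels (absolute %, comparative estimate on
  a log10 axis with a line at no-difference, data table); rows ordered
  with the highest point estimate at the top, alphabetical on ties. The
  absolute axis defaults to `[0, max% × 1.1]`: stretching rare events over
  a 0–100 axis hides them. The data table can sit centrally instead. At
  most three active arms, jittered; more are refused as illegible.
* **Stacked bar chart** — horizontal, arms adjacent per event, the most
  severe segment nearest the axis so cumulative severe-plus-moderate
  comparisons read off directly; bars labelled with participant counts;
  the severity gradient runs dark to light and survives grayscale.
  Events are ordered by descending frequency by default (configurable).
* **Bar chart** — events-per-participant distribution; side-by-side bars
  for two arms, stacked per-arm panels with shared axes beyond two.
* **Kaplan-Meier plot** — within-arm cloglog bands, the extended at-risk
  table aligned beneath, and a reversed-axis option plotting 1 − S(t) for
  rare events.
* **MCF plot** — same chassis, non-decreasing, with a bands-off option
  because overlaid bands for several arms are unreadable.
* **Survival ratio plot** — step curve, percentile bands, reference line
  at unity, and a bottom indicator bar that switches colour (or hatches,
  in grayscale) wherever the band excludes the null.
* **Line graph / violin / density** — normal-limit reference lines; the
  violin overlays median circle, narrow IQR box and min–max whiskers on a
  mirrored density, with a half-violin option that drops the redundant
  mirror image; cells with fewer than two distinct values degrade to
  point-plus-whisker.
* **Scatterplot matrix** — baseline vs maximum per outcome, dashed normal
  limits forming quadrants, per-arm symbols with transparency (solid
  points occlude), and participant-id labels on points outside the normal
  limits, since the off-diagonal quadrants are where the signal lives.

The default palette is colour-blind safe; `grayscale = TRUE` switches to
grey shades with distinct line types and point shapes per arm, so no plot
depends on colour alone. Figures export vector-first (SVG, falling back to
PDF where cairo is unavailable) with PNG as an option, always alongside
their companion CSV tables.

## The decision tree

`recommend_plot()` maps outcome characteristics to endorsed plots: binary
multiple → dot plot (stacked bar chart when severity matters); count →
bar chart regardless of multiplicity; single binary events also route to
the bar chart of per-participant counts. Continuous: multiple outcomes →
scatterplot matrix; a single repeated outcome → line graph, or violin
when the distribution is far from normal or of interest in itself (each
recommendation notes the other as the alternative); a single time point →
kernel density plot. Time-to-event: a single outcome → Kaplan-Meier *and*
survival ratio plot together (absolute and relative views); recurrent →
MCF plot; multiple time-to-event outcomes → an explicit empty
recommendation, because no endorsed display handles them simultaneously.
Finer branches of the original tree (emerging versus prespecified events)
collapse onto the same plots and are not separate inputs; that is a
documented simplification, not an oversight. The recommendation is
advisory — the trial team decides, and crude numbers should always be
examined alongside any plot.

## Synthetic trials

`simulate_trial()` generates datasets with known ground truth. Recurrent
events follow homogeneous Poisson processes at arm-specific rates over
each participant's observed window (onset days uniform within it), with
an optional susceptibility probability thinning the process; severities
are i.i.d. draws from the configured mixture; dropout is exponential and
independent of events (matching the non-informative-censoring assumption
of the estimators it exercises); laboratory values are a participant-level
Gaussian baseline plus an arm-by-visit shift plus residual noise. One
master seed drives deterministic substreams per component, so adding a
laboratory outcome leaves the event draws untouched.

The default configuration is a 300-per-arm placebo-controlled year with
10%/year dropout, six body systems spanning common (≈1.6
events/participant-year) to rare (≈0.1) with mild-dominated severity
mixtures, and an eosinophil-like count that falls sharply under the
intervention while placebo stays near an elevated baseline — magnitudes
chosen once to resemble the infection-heavy respiratory-trial setting the
displays were designed around. What the generator does *not* emulate:
time-varying hazards, event-dependent dropout, competing risks,
within-participant correlation beyond the susceptibility flag, or
dictionary-coded term structure. Tests passing on these data therefore
demonstrate estimator correctness and calibration under the stated
assumptions, not robustness to informative censoring or non-proportional
recurrence.

`fixture_small()` is a fixed eight-participant dataset, fully enumerated
in its help page, against which every derived statistic in the test-suite
is checked by hand.

## Verification and problem sizes

The test-suite checks the estimators against independent brute-force
oracles (explicit loops over records) on 200 random datasets of n ≤ 12 at
10⁻¹², against `survival::survfit` for the product-limit and
counting-process cumulative-hazard routes, and against hand-evaluated
Katz intervals on fixed tables. Calibration checks use: 200 replicates of
200 participants/arm with 500 bootstrap resamples for survival-ratio band
coverage at the median follow-up time under equal exponential hazards;
500 replicates of 200/arm for null coverage of the relative-risk
interval; and 2000/arm for rate-ratio and MCF parameter recovery. These
sizes keep the whole suite around a minute and a half while leaving
Monte-Carlo error (±1.5–3 percentage points on a coverage) well inside
the asserted bands. `scripts/acceptance.R` recomputes the same quantities
from scratch at any seed.

## Known limitations

* No competing-risks estimation, hypothesis testing, multiplicity
  control, regression adjustment, or meta-analytic pooling.
* The half-event correction is the only zero-cell strategy offered.
* KDE boundary bias for non-negative outcomes, as discussed.
* The bootstrap interval type (percentile) and the cloglog KM transform
  are fixed choices; alternatives are not exposed.
* Interactive displays and the non-endorsed plot families (volcano,
  tendril, …) are out of scope by design.
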