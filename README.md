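# harmvis

Graphics and estimators for **harm (adverse-event) outcomes in
parallel-arm randomised controlled trials**. Trial reports usually reduce
harms to frequency tables; harmvis builds the ten visualisations a trial
statistician should reach for instead, each returned together with the
exact summary table it displays:

| outcome type | display |
|---|---|
| binary, multiple events | dot plot (absolute %, comparative estimate, data table) |
| binary, multiple events + severity | stacked bar chart of maximum severity |
| counts per participant | bar chart |
| time-to-event, single event | Kaplan-Meier plot with extended at-risk table, plus survival ratio plot |
| time-to-event, recurrent | mean cumulative function (MCF) plot |
| continuous, repeated | line graph (or violin plot for non-normal outcomes) |
| continuous, single time point | kernel density plot |
| continuous, multiple outcomes | scatterplot matrix of baseline vs maximum |

It is aimed at trial statisticians and anyone preparing safety sections of
trial manuscripts.

## The statistics inside the plots

For a 2×2 table with `a/n1` events in the comparator arm and `b/n2` in the
reference arm, the dot plot's central panel shows the relative risk
`RR = (a/n1)/(b/n2)` with the Katz log-scale Wald interval

```
exp( log RR ± z_{1−α/2} · sqrt(1/a − 1/n1 + 1/b − 1/n2) )
```

(odds ratio, risk difference and incidence rate ratio analogously). When
exactly one arm has zero events, half an event is added to each numerator
and denominator and the estimate is flagged; double-zero events are
dropped with a warning and footnoted.

Time-to-event displays embed the product-limit estimator with Greenwood
variance and complementary log-log confidence bands; the MCF estimator
`M(t) = Σ_{t_j ≤ t} d_j / Y_j` with the Lawless–Nadeau robust variance for
recurrent events; and the survival ratio `S_ref(t) / S_comp(t)` with
pointwise percentile bootstrap bands (participants resampled within arm,
seeded and reproducible). Continuous outcomes get per-visit mean ± SD or
median/IQR summaries and Gaussian kernel densities with the Silverman
`0.9·min(SD, IQR/1.34)·n^{−1/5}` bandwidth.

No hypothesis testing or multiplicity adjustment is performed anywhere:
these are signal-detection displays. Competing risks are not modelled;
see the methods vignette (`vignettes/visualising-harms.Rmd`) for the full
set of assumptions, conventions and limitations.

## Worked example

```r
library(harmvis)

# a synthetic two-arm trial: 300/arm, one year, six body systems
ds <- simulate_trial(default_sim_config(seed = 42))
ds
#> <trial_dataset>
#>   participants : 600 in 2 arm(s) (placebo, intervention)
#>   events       : 1971 record(s), 6 term(s), 6 group(s)
#>   measurements : 2945 record(s), 1 outcome(s)
#>   severity     : mild < moderate < severe

# dot plot: absolute summary + relative risks, ordered highest first
sm  <- summarize_events(ds, "group")
est <- dot_plot_order(effect_table(sm, reference = "placebo", measure = "rr"))
est
#>                                  label   comparison measure point ci_low ci_high
#> 1                respiratory disorders intervention      rr 1.370  1.081   1.738
#> 2                                Other intervention      rr 1.234  0.957   1.591
#> 3          renal and urinary disorders intervention      rr 0.909  0.507   1.630
#> 4          infections and infestations intervention      rr 0.854  0.764   0.955
#> 5 blood and lymphatic system disorders intervention      rr 0.710  0.590   0.854
#> 6           gastrointestinal disorders intervention      rr 0.705  0.592   0.839
fig <- plot_dot(sm, est)
save_figure(fig, "dot_plot")        # dot_plot.svg + companion CSV tables
```

Reading the table: respiratory events are about 37% more frequent under
the intervention (95% CI 1.08 to 1.74, a potential signal worth closer
inspection), while infections, gastrointestinal and blood/lymphatic
events are significantly *less* frequent — intervals entirely below 1.

```r
# Kaplan-Meier with extended at-risk table, for one event of interest
fet    <- first_event_times(ds, "infections and infestations")
curves <- lapply(split(fet, fet$arm), km_estimate)
km     <- km_estimate(fet[fet$arm == "placebo", c("time", "status")])
km$estimate[max(which(km$time <= 100))]
#> [1] 0.7026046    # 70% of placebo participants still infection-free at day 100
plot_km(curves, risk_table(fet, seq(0, 360, 60)))

# which plot should I use?
recommend_plot("time_to_event", "single")
#> Recommended plot(s): kaplan-meier plot; survival ratio plot
#> Note: Kaplan-Meier with extended at-risk table for within-arm estimates;
#>       survival ratio plot alongside it for the direct between-arm comparison.
```

A command-line interface wraps the same functions
(`inst/cli/harmvis`): `simulate`, `summarise`, `plot <kind>` and
`recommend` subcommands write figures, companion CSV tables and a
manifest of resolved options and seeds.

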