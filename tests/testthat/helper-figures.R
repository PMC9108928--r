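# Shared fixture: builds every endorsed figure (and the statistics
# tables behind them) from fixture_small().

fixture_figures <- function(grayscale = FALSE) {
  ds <- fixture_small()
  sm <- summarize_events(ds, "group")
  est <- suppressWarnings(dot_plot_order(effect_table(sm, reference = "B")))
  fet <- first_event_times(ds)
  curves <- lapply(split(fet, fet$arm), km_estimate)
  rt <- risk_table(fet, c(0, 10, 20, 30))
  rec <- recurrent_events(ds)
  ro <- attr(rec, "followup")
  mcurves <- lapply(split(ro, ro$arm), function(r)
    mcf_estimate(rec[rec$arm == r$arm[1], c("participant_id", "time")],
                 setNames(r$followup_days, r$participant_id)))
  sr <- survival_ratio(fet[fet$arm == "A", c("time", "status")],
                       fet[fet$arm == "B", c("time", "status")],
                       n_boot = 50, seed = 3, arms = c("A", "B"))
  tls <- timepoint_summary(ds, "eosinophil count", "mean_sd")
  bm <- baseline_max(ds, "eosinophil count")
  cs <- change_scores(ds, "eosinophil count", "to_maximum")
  list(
    ds = ds, sm = sm, est = est, fet = fet, curves = curves, rt = rt,
    mcurves = mcurves, sr = sr, tls = tls, bm = bm, cs = cs,
    figs = list(
      dot = plot_dot(sm, est, grayscale = grayscale),
      stacked = plot_stacked_severity(max_severity(ds), grayscale = grayscale),
      bars = plot_count_bars(event_counts(ds), grayscale = grayscale),
      km = plot_km(curves, rt, grayscale = grayscale),
      mcf = plot_mcf(mcurves, rt, grayscale = grayscale),
      ratio = plot_survival_ratio(sr, grayscale = grayscale),
      line = plot_line(tls, rng = list(lower = 0.1, upper = 0.5),
                       grayscale = grayscale),
      violin = plot_violin(ds, "eosinophil count", grayscale = grayscale),
      kde = plot_kde(cs, rng = list(lower = 0.1, upper = 0.5),
                     grayscale = grayscale),
      scatter = plot_scatter_matrix(
        list("eosinophil count" = bm), ranges = ds$ranges,
        grayscale = grayscale)))
}
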