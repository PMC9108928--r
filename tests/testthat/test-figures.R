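test_that("all ten plot builders run on the fixture and declare their kind", {
  fx <- fixture_figures()
  kinds <- vapply(fx$figs, function(f) f$kind, character(1))
  expect_setequal(unname(kinds), endorsed_plots())
  for (f in fx$figs) expect_s3_class(f, "harm_figure")
})

test_that("every figure's companion table equals the statistics output", {
  fx <- fixture_figures()
  expect_identical(fx$figs$dot$table$summary, fx$sm)
  expect_identical(fx$figs$dot$table$estimates, fx$est)
  expect_identical(fx$figs$stacked$table, max_severity(fx$ds))
  expect_identical(fx$figs$bars$table, event_counts(fx$ds))
  km_tab <- do.call(rbind, lapply(names(fx$curves), function(a)
    cbind(arm = a, as.data.frame(fx$curves[[a]]))))
  expect_identical(fx$figs$km$table$curves, km_tab)
  expect_identical(fx$figs$km$table$risk_table, fx$rt)
  mcf_tab <- do.call(rbind, lapply(names(fx$mcurves), function(a)
    cbind(arm = a, as.data.frame(fx$mcurves[[a]]))))
  expect_identical(fx$figs$mcf$table$curves, mcf_tab)
  expect_identical(fx$figs$ratio$table, fx$sr)
  expect_identical(fx$figs$line$table, fx$tls)
  expect_identical(fx$figs$violin$table,
                   timepoint_summary(fx$ds, "eosinophil count", "median_iqr"))
  kde_tab <- do.call(rbind, lapply(sort(unique(fx$cs$arm)), function(a) {
    k <- kde_estimate(fx$cs$score[fx$cs$arm == a])
    data.frame(arm = a, grid = k$grid, density = k$density,
               bandwidth = k$bandwidth, stringsAsFactors = FALSE)
  }))
  expect_identical(fx$figs$kde$table, kde_tab)
  expect_identical(fx$figs$scatter$table[["eosinophil count"]], fx$bm)
})

test_that("grayscale mode assigns distinct per-arm styles on every figure", {
  fx <- fixture_figures(grayscale = TRUE)
  for (nm in names(fx$figs)) {
    st <- fx$figs[[nm]]$options$styles
    if (is.null(st)) next  # stacked/ratio differentiate by fill/indicator
    combo <- paste(st$linetype, st$shape, st$colour)
    expect_equal(anyDuplicated(combo), 0, info = nm)
  }
  # stacked bar severity fills are distinct greys
  sf <- fx$figs$stacked$options$severity_fill
  expect_equal(anyDuplicated(sf), 0)
  # ratio indicator uses linetype as the non-colour fallback
  expect_true(isTRUE(fx$figs$ratio$options$grayscale))
})

test_that("dot plot layout follows the ordering, axis and null-line rules", {
  fx <- fixture_figures()
  # rows ordered highest point estimate first
  expect_true(all(diff(fx$est$point) <= 0))
  expect_identical(fx$figs$dot$options$null, 1)
  expect_equal(fx$figs$dot$options$abs_limits, c(0, max(fx$sm$pct) * 1.1))
  # risk-difference variant: null line at 0
  est_rd <- suppressWarnings(dot_plot_order(
    effect_table(fx$sm, reference = "B", measure = "rd")))
  f_rd <- plot_dot(fx$sm, est_rd)
  expect_identical(f_rd$options$null, 0)
  # mismatched event lists are rejected
  est_cut <- fx$est[-1, ]
  for (at in c("dropped", "reference", "alpha"))
    attr(est_cut, at) <- attr(fx$est, at)
  expect_error(plot_dot(fx$sm, est_cut), "different event",
               class = "harmvis_validation_error")
})

test_that("stacked bars put the most severe segment nearest the axis", {
  ds <- fixture_small()
  ms <- max_severity(ds, by = "term")
  f <- plot_stacked_severity(ms)
  lay <- f$options$layout
  for (key in unique(paste(lay$label, lay$arm))) {
    sub <- lay[paste(lay$label, lay$arm) == key, ]
    # segments are stored most-severe first and tile from x = 0
    expect_equal(sub$xmin[1], 0)
    expect_true(all(diff(as.integer(sub$severity)) <= 0))
    if (nrow(sub) > 1)
      expect_equal(sub$xmin[-1], sub$xmax[-nrow(sub)])
  }
  # total bar length equals the % of participants with >= 1 event
  sm <- summarize_events(ds, "term")
  for (key in unique(paste(lay$label, lay$arm))) {
    sub <- lay[paste(lay$label, lay$arm) == key, ]
    expect_equal(max(sub$xmax),
                 sm$pct[sm$label == sub$label[1] & sm$arm == sub$arm[1]])
  }
})

test_that("count bar chart switches layout with the number of arms", {
  ds <- fixture_small()
  f2 <- plot_count_bars(event_counts(ds))
  expect_equal(f2$options$panels, 1L)
  roster3 <- data.frame(participant_id = sprintf("P%d", 1:9),
                        arm = rep(c("a", "b", "c"), each = 3),
                        followup_days = 10)
  ev3 <- data.frame(participant_id = c("P1", "P4", "P4"), term = "t",
                    group = "g", severity = "mild", onset_day = 1)
  ds3 <- trial_dataset(roster3, ev3)
  f3 <- plot_count_bars(event_counts(ds3))
  expect_equal(f3$options$panels, 3L)
})

test_that("km plot validates its risk table and supports the reversed axis", {
  fx <- fixture_figures()
  rt_bad <- risk_table(data.frame(time = 1, status = 1, arm = "Z"), c(0, 5))
  expect_error(plot_km(fx$curves, rt_bad), "match",
               class = "harmvis_validation_error")
  f_rev <- plot_km(fx$curves, fx$rt, reversed_axis = TRUE)
  expect_true(f_rev$options$reversed_axis)
  # single all-censored arm: flat line at 1 (zero-step curve renders)
  flat <- km_estimate(data.frame(time = c(10, 20), status = 0), arm = "solo")
  f_flat <- plot_km(list(solo = flat))
  expect_s3_class(f_flat, "harm_figure")
  # mcf bands can be suppressed for multi-arm clarity
  f_nb <- plot_mcf(fx$mcurves, fx$rt, bands = FALSE)
  expect_false(f_nb$options$bands)
})

test_that("survival ratio indicator segments mirror the excludes_unity flags", {
  fx <- fixture_figures()
  seg <- fx$figs$ratio$options$indicator
  rc <- as.data.frame(fx$sr)
  expect_equal(seg$flag, rc$excludes_unity[-nrow(rc)])
  expect_equal(nrow(seg), nrow(rc) - 1)
})

test_that("kde plot draws reference lines at the configured normal limits", {
  set.seed(5)
  vals <- list(placebo = rnorm(60, 250, 60), trt = c(rnorm(50, 260, 60),
                                                     rnorm(10, 600, 80)))
  f <- plot_kde(vals, rng = list(lower = NA, upper = 390))
  built <- ggplot_build(f$figure)
  xint <- unlist(lapply(built$data, function(d)
    if ("xintercept" %in% names(d)) d$xintercept))
  expect_true(390 %in% xint)
  # identical samples give identical curves
  f_same <- plot_kde(list(a = vals$placebo, b = vals$placebo))
  ta <- f_same$table[f_same$table$arm == "a", c("grid", "density")]
  tb <- f_same$table[f_same$table$arm == "b", c("grid", "density")]
  expect_equal(ta, tb, ignore_attr = "row.names")
})

test_that("scatter matrix labels abnormal points and only those", {
  roster <- data.frame(participant_id = c("P1", "P2"), arm = c("a", "b"),
                       followup_days = 10)
  meas <- data.frame(participant_id = rep(c("P1", "P2"), each = 2),
                     outcome = "alt", visit_time = c(0, 5, 0, 5),
                     value = c(30, 35, 32, 80))  # P2 abnormal on treatment
  rng <- data.frame(outcome = "alt", lower = 10, upper = 50, units = "U/L")
  ds <- trial_dataset(roster, measurements = meas, ranges = rng)
  bm <- baseline_max(ds, "alt")
  f <- plot_scatter_matrix(list(alt = bm), ranges = rng)
  expect_identical(f$options$labelled, "P2")
  expect_equal(f$options$panels, 1L)
  # all within limits: nothing labelled
  rng_wide <- data.frame(outcome = "alt", lower = 0, upper = 1000,
                         units = "U/L")
  f2 <- plot_scatter_matrix(list(alt = bm), ranges = rng_wide)
  expect_length(f2$options$labelled, 0)
})

test_that("figures and companion tables can be written to disk", {
  fx <- fixture_figures()
  dir <- withr::local_tempdir()
  files <- save_figure(fx$figs$km, file.path(dir, "km"),
                       formats = c("png", "csv"))
  expect_true(file.exists(file.path(dir, "km.png")))
  expect_true(file.exists(file.path(dir, "km_curves.csv")))
  expect_true(file.exists(file.path(dir, "km_risk_table.csv")))
})
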