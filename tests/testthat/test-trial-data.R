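test_that("CSV round-trip preserves the dataset", {
  ds <- fixture_small()
  dir <- withr::local_tempdir()
  write_trial(ds, dir)
  back <- read_trial(file.path(dir, "roster.csv"),
                     file.path(dir, "events.csv"),
                     file.path(dir, "measurements.csv"),
                     file.path(dir, "ranges.csv"))
  expect_equal(back$roster, ds$roster)
  expect_equal(back$events, ds$events)
  expect_equal(back$measurements, ds$measurements)
  expect_equal(back$ranges, ds$ranges)
  expect_identical(back$severity_scale, ds$severity_scale)
})

test_that("validation rejects malformed tables with row-addressed messages", {
  ds <- fixture_small()
  bad_sev <- ds$events
  bad_sev$severity[3] <- "catastrophic"
  expect_error(trial_dataset(ds$roster, bad_sev, ds$measurements, ds$ranges),
               "catastrophic", class = "harmvis_validation_error")
  expect_error(trial_dataset(ds$roster, bad_sev, ds$measurements, ds$ranges),
               "row 3")

  bad_onset <- ds$events
  bad_onset$onset_day[1] <- 400
  expect_error(trial_dataset(ds$roster, bad_onset),
               "follow-up", class = "harmvis_validation_error")

  orphan <- rbind(ds$events,
                  data.frame(participant_id = "ZZ", term = "x", group = "g",
                             severity = "mild", onset_day = 1))
  expect_error(trial_dataset(ds$roster, orphan), "not in the roster",
               class = "harmvis_validation_error")

  dup <- rbind(ds$roster, ds$roster[1, ])
  expect_error(trial_dataset(dup), "duplicate",
               class = "harmvis_validation_error")

  neg <- ds$roster; neg$followup_days[2] <- -1
  expect_error(trial_dataset(neg), "non-negative",
               class = "harmvis_validation_error")
})

test_that("missing body-system group defaults to Other", {
  ds <- fixture_small()
  ev <- ds$events
  ev$group[1] <- NA
  ev$group[2] <- ""
  d2 <- trial_dataset(ds$roster, ev)
  expect_identical(d2$events$group[1:2], c("Other", "Other"))
})

test_that("first_event_times picks the earliest onset and censors the rest", {
  ds <- fixture_small()
  fet <- first_event_times(ds, "any")
  expect_equal(nrow(fet), nrow(ds$roster))
  # A1 has headaches at days 5 and 12 -> first event at 5
  expect_equal(fet[fet$participant_id == "A1", c("time", "status")],
               data.frame(time = 5, status = 1L),
               ignore_attr = "row.names")
  # A3 has no events -> censored at follow-up 30
  expect_equal(fet[fet$participant_id == "A3", c("time", "status")],
               data.frame(time = 30, status = 0L),
               ignore_attr = "row.names")
  # selector by term and by group both give one row per participant
  for (sel in c("headache", "gastro", "rash"))
    expect_equal(nrow(first_event_times(ds, sel)), 8)
  expect_error(first_event_times(ds, "no-such-thing"), "available",
               class = "harmvis_validation_error")
})

test_that("max_severity counts each participant once at their highest grade", {
  ds <- fixture_small()
  ms <- max_severity(ds, by = "term")
  # A1: mild + moderate headache -> once, moderate
  a_head <- ms[ms$arm == "A" & ms$label == "headache", ]
  expect_equal(nrow(a_head), 1)
  expect_equal(as.character(a_head$severity), "moderate")
  expect_equal(a_head$n, 1)
  # severe + mild + mild of one term -> severe
  roster <- data.frame(participant_id = "X", arm = "A", followup_days = 10)
  ev <- data.frame(participant_id = "X", term = "t", group = "g",
                   severity = c("severe", "mild", "mild"),
                   onset_day = c(1, 2, 3))
  ms2 <- max_severity(trial_dataset(roster, ev), by = "term")
  expect_equal(as.character(ms2$severity), "severe")
  expect_equal(ms2$n, 1)
  # participants with no events contribute nothing: total counted
  # participants equals participants with >= 1 event (6 of 8)
  expect_equal(sum(ms$n), 6)
  # counts over grades sum to participants with >= 1 event of the term
  sm <- summarize_events(ds, "term")
  for (lab in unique(ms$label)) for (a in unique(ms$arm)) {
    expect_equal(sum(ms$n[ms$label == lab & ms$arm == a]),
                 sm$n_participants[sm$label == lab & sm$arm == a])
  }
})

test_that("event_counts bins every participant exactly once", {
  ds <- fixture_small()
  ec <- event_counts(ds)
  # arm A: A1 has 2 events, A2 1, A3 0, A4 1
  a <- ec[ec$arm == "A", ]
  expect_equal(a$k, c(0, 1, 2))
  expect_equal(a$n, c(1, 2, 1))
  expect_equal(a$pct, c(25, 50, 25))
  # arm B: B1 1, B2 3, B3 0, B4 0
  b <- ec[ec$arm == "B", ]
  expect_equal(b$k, c(0, 1, 3))
  expect_equal(b$n, c(2, 1, 1))
  for (a in unique(ec$arm))
    expect_equal(sum(ec$pct[ec$arm == a]), 100, tolerance = 1e-9)
  expect_equal(sum(ec$n), nrow(ds$roster))
  # an arm with no events collapses to a single k = 0 bin at 100%
  quiet <- trial_dataset(data.frame(participant_id = letters[1:10],
                                    arm = "A", followup_days = 30))
  ecq <- event_counts(quiet)
  expect_equal(ecq$k, 0)
  expect_equal(ecq$pct, 100)
})

test_that("baseline_max pairs baseline with the post-baseline maximum", {
  roster <- data.frame(participant_id = c("P1", "P2", "P3"),
                       arm = "A", followup_days = 30)
  meas <- data.frame(
    participant_id = c("P1", "P1", "P1", "P2", "P3", "P3"),
    outcome = "alt",
    visit_time = c(0, 10, 20, 0, 0, 10),
    value = c(100, 150, 120, 90, 80, 80))
  ds <- trial_dataset(roster, measurements = meas)
  bm <- baseline_max(ds, "alt")
  expect_equal(bm$baseline[bm$participant_id == "P1"], 100)
  expect_equal(bm$maximum[bm$participant_id == "P1"], 150)
  # constant series: baseline equals maximum
  expect_equal(bm$baseline[bm$participant_id == "P3"],
               bm$maximum[bm$participant_id == "P3"])
  # P2 has baseline only -> excluded with a reason
  expect_false("P2" %in% bm$participant_id)
  excl <- attr(bm, "excluded")
  expect_equal(excl$reason[excl$participant_id == "P2"], "no post-baseline")
  expect_error(baseline_max(ds, "nope"), "available",
               class = "harmvis_validation_error")
})
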