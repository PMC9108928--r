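test_that("km_estimate matches the hand product-limit calculation", {
  # times (1 event, 2 event, 3 censored, 4 event), n = 4
  rec <- data.frame(time = c(1, 2, 3, 4), status = c(1, 1, 0, 1))
  km <- km_estimate(rec)
  expect_equal(km$time, c(1, 2, 4))
  expect_equal(km$estimate, c(3 / 4, 1 / 2, 0))
  expect_equal(km$n_risk, c(4, 3, 1))
  # fixture arm A: first events at 3 (A4), 5 (A1), 10 (A2); A3 censored 30
  ds <- fixture_small()
  fet <- first_event_times(ds)
  kmA <- km_estimate(fet[fet$arm == "A", c("time", "status")])
  expect_equal(kmA$time, c(3, 5, 10))
  expect_equal(kmA$estimate, c(3 / 4, 1 / 2, 1 / 4))
})

test_that("km_estimate boundary behaviour: all censored and no censoring", {
  allc <- km_estimate(data.frame(time = c(5, 8, 9), status = 0))
  expect_equal(nrow(allc), 0)  # S(t) = 1 everywhere
  # no censoring: S(t) = 1 - ECDF(t) at every event time
  set.seed(3)
  t <- sample(1:20, 10, replace = TRUE)
  km <- km_estimate(data.frame(time = t, status = 1))
  expect_equal(km$estimate, 1 - ecdf(t)(km$time))
  expect_error(km_estimate(data.frame(time = numeric(), status = integer())),
               class = "harmvis_validation_error")
})

test_that("km bands stay within [0, 1] and bracket the estimate", {
  set.seed(21)
  for (i in 1:20) {
    rec <- random_records()
    km <- km_estimate(rec)
    if (!nrow(km)) next
    expect_true(all(km$ci_low >= 0 & km$ci_high <= 1))
    expect_true(all(km$ci_low <= km$estimate + 1e-12))
    expect_true(all(km$estimate <= km$ci_high + 1e-12))
    expect_true(all(diff(km$estimate) <= 1e-12))  # non-increasing
  }
})

test_that("km agrees with survival::survfit point estimates and variance", {
  skip_if_not_installed("survival")
  set.seed(31)
  for (i in 1:20) {
    rec <- random_records(10)
    if (!sum(rec$status)) next
    km <- km_estimate(rec)
    sf <- survival::survfit(survival::Surv(time, status) ~ 1, data = rec)
    sfs <- summary(sf, times = km$time)
    expect_equal(km$estimate, sfs$surv, tolerance = 1e-12)
    expect_equal(sqrt(km$variance)[km$estimate > 0],
                 sfs$std.err[km$estimate > 0], tolerance = 1e-8)
  }
})

test_that("extended risk table counts and conserves the arm size", {
  rec <- data.frame(time = c(1, 2, 3, 4), status = c(1, 1, 0, 1),
                    arm = "A")
  rt <- risk_table(rec, c(0, 2, 4))
  expect_equal(rt$n_risk, c(4, 2, 0))
  expect_equal(rt$cum_events, c(0, 2, 3))
  expect_equal(rt$cum_censored, c(0, 0, 1))
  # t = 0 boundary and beyond-follow-up conservation
  ds <- fixture_small()
  fet <- first_event_times(ds)
  rt2 <- risk_table(fet, c(0, 10, 20, 30, 40))
  for (a in unique(rt2$arm)) {
    sub <- rt2[rt2$arm == a, ]
    n <- sum(fet$arm == a)
    expect_equal(sub$n_risk[sub$time == 0], n)
    expect_equal(sub$cum_events[sub$time == 0], 0)
    expect_true(all(sub$n_risk + sub$cum_events + sub$cum_censored == n))
    expect_true(all(diff(sub$n_risk) <= 0))
    expect_true(all(diff(sub$cum_events) >= 0))
    expect_true(all(diff(sub$cum_censored) >= 0))
    expect_equal(sub$n_risk[sub$time == 40], 0)
  }
  expect_error(risk_table(rec, c(5, 2)), class = "harmvis_validation_error")
})

test_that("mcf_estimate matches the hand d(t)/Y(t) increments", {
  # 2 participants: A events at days 1 and 2, B none, both followed 3 days
  ev <- data.frame(participant_id = c("A", "A"), time = c(1, 2))
  fup <- c(A = 3, B = 3)
  mcf <- mcf_estimate(ev, fup)
  expect_equal(mcf$time, c(1, 2))
  expect_equal(mcf$estimate, c(0.5, 1.0))
  expect_equal(mcf$n_risk, c(2, 2))
  # no events: MCF identically 0 (zero rows)
  none <- mcf_estimate(NULL, fup)
  expect_equal(nrow(none), 0)
  expect_identical(attr(none, "kind"), "mcf")
  expect_error(mcf_estimate(ev, numeric()), class = "harmvis_validation_error")
})

test_that("mcf conserves total events per participant without censoring", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    ids <- letters[seq_len(n)]
    fup <- setNames(rep(20, n), ids)
    k <- sample(0:4, n, replace = TRUE)
    ev <- data.frame(participant_id = rep(ids, k),
                     time = sample(1:20, sum(k), replace = TRUE))
    if (!nrow(ev)) next
    mcf <- mcf_estimate(ev, fup)
    expect_equal(tail(mcf$estimate, 1), nrow(ev) / n)
    expect_true(all(diff(mcf$estimate) >= 0))
    expect_true(all(mcf$ci_low >= 0))
    expect_true(all(mcf$ci_low <= mcf$estimate + 1e-12 &
                      mcf$estimate <= mcf$ci_high + 1e-12))
  }
})

test_that("mcf point estimate agrees with the counting-process Nelson-Aalen", {
  skip_if_not_installed("survival")
  set.seed(43)
  n <- 8
  ids <- sprintf("p%d", 1:n)
  fup <- setNames(sample(5:15, n, replace = TRUE), ids)
  k <- sample(0:3, n, replace = TRUE)
  ev <- data.frame(participant_id = rep(ids, k),
                   time = unlist(lapply(seq_len(n), function(i)
                     if (k[i]) sample(seq_len(fup[i]), k[i]) else numeric())))
  mcf <- mcf_estimate(ev, fup)
  # counting-process layout: one interval per gap between a participant's
  # ordered event times, closing at follow-up
  rows <- do.call(rbind, lapply(ids, function(id) {
    tt <- sort(ev$time[ev$participant_id == id])
    start <- c(0, tt); stop <- c(tt, fup[id])
    keep <- stop > start
    data.frame(id = id, start = start[keep], stop = stop[keep],
               status = c(rep(1, length(tt)), 0)[keep])
  }))
  sf <- survival::survfit(survival::Surv(start, stop, status) ~ 1,
                          data = rows, id = rows$id)
  na <- sf$cumhaz[match(mcf$time, sf$time)]
  expect_equal(mcf$estimate, na, tolerance = 1e-12)
})

test_that("survival_ratio of identical arms is unity with inclusive bands", {
  ds <- fixture_small()
  fet <- first_event_times(ds)
  armA <- fet[fet$arm == "A", c("time", "status")]
  sr <- survival_ratio(armA, armA, n_boot = 200, seed = 5)
  expect_true(all(sr$estimate == 1))
  expect_false(any(sr$excludes_unity))
  expect_true(all(sr$ci_low <= 1 & sr$ci_high >= 1))
})

test_that("survival_ratio point curve is the ratio of the two KM curves", {
  ds <- fixture_small()
  fet <- first_event_times(ds)
  a <- fet[fet$arm == "A", c("time", "status")]
  b <- fet[fet$arm == "B", c("time", "status")]
  sr <- survival_ratio(a, b, n_boot = 10, seed = 1)
  kma <- km_estimate(a); kmb <- km_estimate(b)
  s_at <- function(km, t) vapply(t, function(ti) {
    i <- which(km$time <= ti)
    if (length(i)) km$estimate[max(i)] else 1
  }, numeric(1))
  expect_equal(sr$estimate, s_at(kma, sr$time) / s_at(kmb, sr$time))
})

test_that("survival_ratio swap gives the pointwise reciprocal and seeds reproduce", {
  set.seed(51)
  t1 <- rexp(40, 0.2); t2 <- rexp(40, 0.35)
  a <- data.frame(time = pmin(t1, 10), status = as.integer(t1 <= 10))
  b <- data.frame(time = pmin(t2, 10), status = as.integer(t2 <= 10))
  s1 <- survival_ratio(a, b, n_boot = 100, seed = 9)
  s2 <- survival_ratio(b, a, n_boot = 100, seed = 9)
  expect_equal(s1$time, s2$time)
  expect_equal(s1$estimate, 1 / s2$estimate)
  # bit-reproducible with the same seed
  s3 <- survival_ratio(a, b, n_boot = 100, seed = 9)
  expect_identical(as.data.frame(s1), as.data.frame(s3))
  # seed is mandatory
  expect_error(survival_ratio(a, b, n_boot = 10),
               class = "harmvis_validation_error")
})

test_that("survival_ratio difference mode uses a null of zero", {
  ds <- fixture_small()
  fet <- first_event_times(ds)
  a <- fet[fet$arm == "A", c("time", "status")]
  b <- fet[fet$arm == "B", c("time", "status")]
  sd <- survival_ratio(a, b, n_boot = 50, seed = 2, type = "difference")
  expect_identical(attr(sd, "null"), 0)
  kma <- km_estimate(a)
  expect_lte(max(abs(sd$estimate)), 1)
})
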