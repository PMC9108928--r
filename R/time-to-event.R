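# Product-limit (Kaplan-Meier) estimation with Greenwood variance and
# complementary log-log confidence bands, extended at-risk tables, the mean
# cumulative function for recurrent events with the Lawless-Nadeau robust
# variance, and the bootstrap survival-ratio comparison between arms.
#
# Tie convention: events are processed before censorings at equal times,
# i.e. a participant censored at t is still at risk for events at t.

# fast core: distinct event times, risk sets, deaths, survival steps
km_compute <- function(time, status) {
  st <- sort(time)
  n <- length(time)
  et <- sort(unique(time[status == 1]))
  if (!length(et))
    return(list(time = numeric(), n_risk = integer(), n_event = integer(),
                estimate = numeric(), n = n))
  n_risk <- n - findInterval(et, st, left.open = TRUE)
  n_event <- tabulate(match(time[status == 1], et), nbins = length(et))
  list(time = et, n_risk = n_risk, n_event = n_event,
       estimate = cumprod(1 - n_event / n_risk), n = n)
}

# evaluate a step function S (value before first step = init) at points t
eval_step <- function(t, steps_time, steps_value, init = 1) {
  c(init, steps_value)[findInterval(t, steps_time) + 1]
}

as_records <- function(records) {
  if (is.data.frame(records)) {
    if (!all(c("time", "status") %in% names(records)))
      stop_validation("records need `time` and `status` columns")
    records
  } else stop_validation("records must be a data frame of (time, status)")
}

#' Kaplan-Meier product-limit estimate
#'
#' Event-free probability over time for one arm, with Greenwood variance
#' and pointwise confidence limits on the complementary log-log scale
#' (which keeps the bands inside \[0, 1\]).
#'
#' @param records data frame with columns `time` (non-negative) and
#'   `status` (1 = event, 0 = censored), e.g. one arm of
#'   [first_event_times()].
#' @param alpha two-sided level for the bands.
#' @param arm optional arm label stored with the curve.
#' @return A data frame of class `survival_curve` with one row per distinct
#'   event time: `time`, `n_risk`, `n_event`, `estimate`, `variance`,
#'   `ci_low`, `ci_high`. Attributes: `kind = "km"`, `n`, `arm`, `alpha`,
#'   `max_time` (largest observed time). With no events the curve has zero
#'   rows (S(t) = 1 everywhere).
#' @export
km_estimate <- function(records, alpha = 0.05, arm = NULL) {
  records <- as_records(records)
  if (!nrow(records)) stop_validation("no records supplied")
  if (any(records$time < 0)) stop_validation("times must be non-negative")
  fit <- km_compute(records$time, records$status)
  z <- qnorm(1 - alpha / 2)
  s <- fit$estimate
  gw <- cumsum(fit$n_event / (fit$n_risk * pmax(fit$n_risk - fit$n_event, 0)))
  variance <- s^2 * gw
  ci_low <- ci_high <- s
  pos <- s > 0 & s < 1
  if (any(pos)) {
    se_cll <- sqrt(gw[pos]) / abs(log(s[pos]))
    ci_low[pos] <- s[pos]^exp(z * se_cll)
    ci_high[pos] <- s[pos]^exp(-z * se_cll)
  }
  zero <- s == 0
  variance[zero] <- 0; ci_low[zero] <- 0; ci_high[zero] <- 0
  out <- data.frame(time = fit$time, n_risk = fit$n_risk,
                    n_event = fit$n_event, estimate = s,
                    variance = variance, ci_low = ci_low, ci_high = ci_high)
  structure(out, kind = "km", n = fit$n, arm = arm, alpha = alpha,
            max_time = max(records$time),
            class = c("survival_curve", "data.frame"))
}

#' Extended at-risk table
#'
#' For each arm and grid time: participants still at risk, cumulative
#' number censored, and cumulative number with the event. Events and
#' censorings occurring at exactly `t` are included in the cumulative
#' columns at `t`; `at risk = arm size - (cum events + cum censored)` so
#' the three columns conserve the arm size at every grid point.
#'
#' @param records data frame with `time`, `status` and `arm` columns (e.g.
#'   [first_event_times()] output), or a named list of per-arm
#'   `(time, status)` data frames.
#' @param timepoints increasing grid starting at 0.
#' @return Data frame of class `risk_table`: `arm`, `time`, `n_risk`,
#'   `cum_events`, `cum_censored`.
#' @export
risk_table <- function(records, timepoints) {
  if (is.data.frame(records)) {
    if (!"arm" %in% names(records))
      stop_validation("records data frame needs an `arm` column")
    records <- split(records[, c("time", "status")], records$arm)
  }
  if (is.unsorted(timepoints, strictly = TRUE) || timepoints[1] < 0)
    stop_validation("timepoints must be strictly increasing and start at >= 0")
  rows <- lapply(names(records), function(a) {
    r <- as_records(records[[a]])
    n <- nrow(r)
    evt <- sort(r$time[r$status == 1])
    cens <- sort(r$time[r$status == 0])
    cum_events <- findInterval(timepoints, evt)
    cum_censored <- findInterval(timepoints, cens)
    data.frame(arm = a, time = timepoints,
               n_risk = n - cum_events - cum_censored,
               cum_events = cum_events, cum_censored = cum_censored,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("risk_table", "data.frame")
  out
}

#' Mean cumulative function for recurrent events
#'
#' Non-parametric estimate of the expected cumulative number of events per
#' participant over time: at each distinct event time the function
#' increments by (events at t) / (participants still under observation at
#' t). Variance uses the Lawless-Nadeau robust (sandwich) estimator, which
#' accommodates within-participant correlation of recurrent events;
#' confidence limits are computed on the log scale so the lower band stays
#' non-negative.
#'
#' @param event_times data frame with `participant_id` and `time` columns,
#'   one row per event (recurrences allowed), e.g. [recurrent_events()].
#' @param followup named numeric vector of follow-up times (names are
#'   participant ids), or a data frame with `participant_id` and
#'   `followup_days`. Every participant's follow-up must be at least their
#'   largest event time; participants with no events still contribute to
#'   the risk sets.
#' @param alpha two-sided level.
#' @param arm optional label.
#' @return A data frame of class `survival_curve` with `kind = "mcf"`:
#'   `time`, `n_risk`, `n_event`, `estimate` (non-decreasing from 0),
#'   `variance`, `ci_low`, `ci_high`.
#' @export
mcf_estimate <- function(event_times, followup, alpha = 0.05, arm = NULL) {
  if (is.data.frame(followup)) {
    fcol <- intersect(c("followup_days", "followup", "time"), names(followup))[1]
    followup <- setNames(followup[[fcol]], followup$participant_id)
  }
  if (!length(followup)) stop_validation("empty roster")
  ids <- names(followup)
  ev <- if (is.null(event_times) || !nrow(as.data.frame(event_times)))
    data.frame(participant_id = character(), time = numeric()) else
      as.data.frame(event_times)
  if (nrow(ev)) {
    if (!all(ev$participant_id %in% ids))
      stop_validation("event participant missing from followup roster")
    if (any(ev$time > followup[ev$participant_id]))
      stop_validation("event time exceeds participant follow-up")
  }
  n <- length(followup)
  et <- sort(unique(ev$time))
  if (!length(et)) {
    out <- data.frame(time = numeric(), n_risk = integer(),
                      n_event = integer(), estimate = numeric(),
                      variance = numeric(), ci_low = numeric(),
                      ci_high = numeric())
    return(structure(out, kind = "mcf", n = n, arm = arm, alpha = alpha,
                     max_time = max(followup),
                     class = c("survival_curve", "data.frame")))
  }
  K <- length(et)
  sf <- sort(unname(followup))
  Y <- n - findInterval(et, sf, left.open = TRUE)  # under observation at t
  d <- tabulate(match(ev$time, et), nbins = K)
  m <- d / Y
  mcf <- cumsum(m)

  # robust variance: sum_i [ sum_{t_j <= min(t, tau_i)} (d_ij - m_j)/Y_j ]^2
  tab <- table(factor(ev$participant_id, levels = ids),
               factor(ev$time, levels = et))          # n x K event counts
  Acum <- t(apply(sweep(unclass(tab), 2, Y, "/"), 1, cumsum))
  if (K == 1) Acum <- matrix(Acum, nrow = n)
  Cc <- cumsum(m / Y)
  pos <- findInterval(unname(followup), et)           # last event time <= tau_i
  idx <- outer(pos, seq_len(K), pmin)
  B <- matrix(c(0, Cc)[idx + 1], nrow = n)
  variance <- colSums((Acum - B)^2)

  z <- qnorm(1 - alpha / 2)
  ci_low <- ci_high <- mcf
  posm <- mcf > 0 & variance > 0
  ci_low[posm] <- mcf[posm] * exp(-z * sqrt(variance[posm]) / mcf[posm])
  ci_high[posm] <- mcf[posm] * exp(z * sqrt(variance[posm]) / mcf[posm])
  out <- data.frame(time = et, n_risk = Y, n_event = d, estimate = mcf,
                    variance = unname(variance), ci_low = unname(ci_low),
                    ci_high = unname(ci_high))
  rownames(out) <- NULL
  structure(out, kind = "mcf", n = n, arm = arm, alpha = alpha,
            max_time = max(followup),
            class = c("survival_curve", "data.frame"))
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve kind=%s n=%d%s> %d step(s)\n",
              attr(x, "kind"), attr(x, "n"),
              if (!is.null(attr(x, "arm"))) paste0(" arm=", attr(x, "arm")) else "",
              nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Survival ratio between two arms with bootstrap bands
#'
#' Ratio (or difference) of Kaplan-Meier event-free probability estimates,
#' reference arm in the numerator, evaluated on the union of the two arms'
#' event-time grids. Pointwise confidence bands are percentile intervals
#' over `n_boot` resamples of participants drawn with replacement within
#' each arm. Times at which either arm's KM estimate has reached zero are
#' truncated from the ratio grid. The per-time flag `excludes_unity` is
#' `TRUE` where the null value (1 for ratios, 0 for differences) lies
#' outside the band: the plot's bottom indicator bar switches colour there.
#'
#' @param reference,comparator data frames of `(time, status)` records; the
#'   reference arm forms the numerator.
#' @param n_boot number of bootstrap resamples (>= 1).
#' @param alpha two-sided level for the percentile bands.
#' @param seed integer seed; mandatory so bands are reproducible.
#' @param type `"ratio"` or `"difference"`.
#' @param arms optional c(reference, comparator) labels.
#' @return Data frame of class `survival_ratio_curve`: `time`, `estimate`,
#'   `ci_low`, `ci_high`, `excludes_unity`; attributes `type`, `null`,
#'   `n_boot`, `alpha`, `seed`, `arms`.
#' @details A degenerate resample in which an arm is entirely censored
#'   yields S(t) = 1 for that arm and is retained, not rejected. Resamples
#'   in which an arm's estimate hits zero contribute infinite (ratio) or
#'   boundary values at later times; percentile quantiles absorb these.
#' @export
survival_ratio <- function(reference, comparator, n_boot = 1000,
                           alpha = 0.05, seed, type = c("ratio", "difference"),
                           arms = c("reference", "comparator")) {
  type <- match.arg(type)
  if (missing(seed) || is.null(seed))
    stop_validation("a seed is required for the bootstrap bands")
  if (n_boot < 1) stop_validation("n_boot must be >= 1")
  r1 <- as_records(reference); r2 <- as_records(comparator)
  if (!nrow(r1) || !nrow(r2)) stop_validation("both arms must be non-empty")

  f1 <- km_compute(r1$time, r1$status)
  f2 <- km_compute(r2$time, r2$status)
  grid <- sort(unique(c(0, f1$time, f2$time)))
  s1 <- eval_step(grid, f1$time, f1$estimate)
  s2 <- eval_step(grid, f2$time, f2$estimate)
  keep <- if (type == "ratio") s1 > 0 & s2 > 0 else rep(TRUE, length(grid))
  grid <- grid[keep]; s1 <- s1[keep]; s2 <- s2[keep]
  est <- if (type == "ratio") s1 / s2 else s1 - s2

  n1 <- nrow(r1); n2 <- nrow(r2)
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, length(grid))
  for (b in seq_len(n_boot)) {
    i1 <- sample.int(n1, n1, replace = TRUE)
    i2 <- sample.int(n2, n2, replace = TRUE)
    b1 <- km_compute(r1$time[i1], r1$status[i1])
    b2 <- km_compute(r2$time[i2], r2$status[i2])
    bs1 <- eval_step(grid, b1$time, b1$estimate)
    bs2 <- eval_step(grid, b2$time, b2$estimate)
    boot[b, ] <- if (type == "ratio") bs1 / bs2 else bs1 - bs2
  }
  probs <- c(alpha / 2, 1 - alpha / 2)
  bands <- apply(boot, 2, function(col) {
    col <- col[!is.nan(col)]  # 0/0 in fully-evented resamples; +Inf is kept
    if (!length(col)) return(c(NA_real_, NA_real_))
    quantile(col, probs = probs, names = FALSE, type = 7)
  })
  null <- if (type == "ratio") 1 else 0
  out <- data.frame(time = grid, estimate = est,
                    ci_low = bands[1, ], ci_high = bands[2, ])
  out$excludes_unity <- out$ci_low > null | out$ci_high < null
  structure(out, type = type, null = null, n_boot = n_boot, alpha = alpha,
            seed = seed, arms = arms,
            class = c("survival_ratio_curve", "data.frame"))
}
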