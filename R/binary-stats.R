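# Absolute summaries and comparative estimates for binary/count harm
# outcomes: the computational core of the dot plot, stacked bar chart and
# bar chart. Ratio measures use Wald intervals on the log scale (Katz);
# the risk difference uses the identity scale. The 95% interval is the
# point estimate +/- 1.96 standard errors (z at the configured alpha).

#' Per-event absolute summary by arm
#'
#' Number of participants with at least one event, number of events, and
#' percentage of the arm roster, for every distinct term or body-system
#' group, zero-filled across arms.
#'
#' @param dataset a `trial_dataset`.
#' @param by `"group"` or `"term"`.
#' @return Data frame of class `event_summary`: `label`, `arm`, `arm_n`,
#'   `n_participants`, `n_events`, `pct`.
#' @export
summarize_events <- function(dataset, by = c("group", "term")) {
  stopifnot(inherits(dataset, "trial_dataset"))
  by <- match.arg(by)
  ev <- dataset$events
  arms <- sort(unique(dataset$roster$arm))
  arm_sizes <- table(dataset$roster$arm)
  labels <- sort(unique(ev[[by]]))
  out <- expand.grid(label = labels, arm = arms, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  if (nrow(ev)) {
    ev$label <- ev[[by]]
    ev$arm <- dataset$roster$arm[match(ev$participant_id,
                                       dataset$roster$participant_id)]
    key <- paste(out$label, out$arm, sep = "\r")
    evkey <- paste(ev$label, ev$arm, sep = "\r")
    n_events <- table(evkey)
    pkey <- unique(paste(evkey, ev$participant_id, sep = "\r"))
    n_part <- table(sub("\r[^\r]*$", "", pkey))
    out$n_participants <- as.integer(ifelse(is.na(n_part[key]), 0, n_part[key]))
    out$n_events <- as.integer(ifelse(is.na(n_events[key]), 0, n_events[key]))
  } else {
    out$n_participants <- integer(0)
    out$n_events <- integer(0)
  }
  out$arm_n <- as.integer(arm_sizes[out$arm])
  out$pct <- 100 * out$n_participants / out$arm_n
  out <- out[, c("label", "arm", "arm_n", "n_participants", "n_events", "pct")]
  out <- out[order(out$label, out$arm), ]
  rownames(out) <- NULL
  class(out) <- c("event_summary", "data.frame")
  out
}

new_effect_estimate <- function(measure, point, ci_low, ci_high, corrected,
                                alpha, inputs) {
  structure(list(measure = measure, point = point, ci_low = ci_low,
                 ci_high = ci_high, corrected = corrected, alpha = alpha,
                 null = if (measure == "rd") 0 else 1, inputs = inputs),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  lbl <- c(rr = "relative risk", or = "odds ratio", rd = "risk difference",
           irr = "incidence rate ratio")[x$measure]
  cat(sprintf("%s %.4g (%.0f%% CI %.4g to %.4g)%s\n", lbl, x$point,
              100 * (1 - x$alpha), x$ci_low, x$ci_high,
              if (x$corrected) " [half-event correction applied]" else ""))
  invisible(x)
}

#' Comparative effect estimate from a 2x2 table
#'
#' Point estimate and Wald confidence interval for the relative risk, odds
#' ratio or risk difference comparing `a/n1` (e.g. treated) with `b/n2`
#' (e.g. control). Ratio measures are estimated on the log scale with the
#' Katz standard error; the risk difference on the identity scale. When
#' `correction = TRUE` and exactly one of `a`, `b` is zero, half an event
#' is added to each numerator and denominator (`a`, `b`, `n1`, `n2`) before
#' estimation and the result is flagged `corrected`.
#'
#' @param a,n1 events and size in the first (numerator) arm.
#' @param b,n2 events and size in the second (reference) arm.
#' @param measure `"rr"`, `"or"` or `"rd"`.
#' @param alpha two-sided level; default 0.05 gives the usual 1.96 z.
#' @param correction apply the half-event zero-cell correction.
#' @return An `effect_estimate` with elements `measure`, `point`, `ci_low`,
#'   `ci_high`, `corrected`, `alpha`, `null`, `inputs`.
#' @section Errors: `a = b = 0` raises a `harmvis_no_estimate` condition:
#'   the row must be dropped (with a warning) rather than estimated.
#' @export
effect_estimate <- function(a, n1, b, n2, measure = c("rr", "or", "rd"),
                            alpha = 0.05, correction = TRUE) {
  measure <- match.arg(measure)
  if (n1 <= 0 || n2 <= 0)
    stop_validation("arm sizes must be positive (got n1 = %s, n2 = %s)", n1, n2)
  if (a < 0 || a > n1 || b < 0 || b > n2)
    stop_validation("event counts must satisfy 0 <= a <= n1 and 0 <= b <= n2")
  if (a == 0 && b == 0)
    stop_no_estimate("no events in either arm: estimate undefined, drop the row")
  inputs <- list(a = a, n1 = n1, b = b, n2 = n2)
  corrected <- FALSE
  if (correction && xor(a == 0, b == 0)) {
    a <- a + 0.5; b <- b + 0.5; n1 <- n1 + 0.5; n2 <- n2 + 0.5
    corrected <- TRUE
  }
  z <- qnorm(1 - alpha / 2)
  p1 <- a / n1; p2 <- b / n2
  if (measure == "rr") {
    point <- p1 / p2
    se <- sqrt(1 / a - 1 / n1 + 1 / b - 1 / n2)
    lo <- exp(log(point) - z * se); hi <- exp(log(point) + z * se)
  } else if (measure == "or") {
    point <- (a * (n2 - b)) / ((n1 - a) * b)
    se <- sqrt(1 / a + 1 / (n1 - a) + 1 / b + 1 / (n2 - b))
    lo <- exp(log(point) - z * se); hi <- exp(log(point) + z * se)
  } else {
    point <- p1 - p2
    se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
    lo <- point - z * se; hi <- point + z * se
  }
  new_effect_estimate(measure, point, lo, hi, corrected, alpha, inputs)
}

#' Incidence rate ratio from event counts and exposure time
#'
#' `(events1/time1) / (events2/time2)` with a log-scale Wald interval,
#' `SE = sqrt(1/events1 + 1/events2)`. When exactly one count is zero and
#' `correction = TRUE`, half an event is added to each count.
#'
#' @param events1,time1 events and total exposure in the numerator arm.
#' @param events2,time2 events and total exposure in the reference arm.
#' @inheritParams effect_estimate
#' @return An `effect_estimate` with `measure = "irr"`.
#' @export
rate_ratio <- function(events1, time1, events2, time2, alpha = 0.05,
                       correction = TRUE) {
  if (time1 <= 0 || time2 <= 0)
    stop_validation("exposure times must be positive")
  if (events1 < 0 || events2 < 0)
    stop_validation("event counts must be non-negative")
  if (events1 == 0 && events2 == 0)
    stop_no_estimate("no events in either arm: rate ratio undefined")
  inputs <- list(events1 = events1, time1 = time1,
                 events2 = events2, time2 = time2)
  corrected <- FALSE
  if (correction && xor(events1 == 0, events2 == 0)) {
    events1 <- events1 + 0.5; events2 <- events2 + 0.5
    corrected <- TRUE
  }
  z <- qnorm(1 - alpha / 2)
  point <- (events1 / time1) / (events2 / time2)
  se <- sqrt(1 / events1 + 1 / events2)
  new_effect_estimate("irr", point,
                      exp(log(point) - z * se), exp(log(point) + z * se),
                      corrected, alpha, inputs)
}

#' Comparative estimates for every event in a summary
#'
#' Applies [effect_estimate()] to each label of an [summarize_events()]
#' table, comparing each non-reference arm against the reference. Events
#' with zero counts in both arms cannot be estimated; they are dropped with
#' a warning and listed in attribute `"dropped"`.
#'
#' @param summary an `event_summary`.
#' @param reference reference arm label (the denominator of ratio measures).
#' @param measure `"rr"`, `"or"` or `"rd"`.
#' @inheritParams effect_estimate
#' @return Data frame of class `effect_table`: `label`, `comparison`,
#'   `measure`, `point`, `ci_low`, `ci_high`, `corrected`.
#' @export
effect_table <- function(summary, reference, measure = c("rr", "or", "rd"),
                         alpha = 0.05, correction = TRUE) {
  stopifnot(inherits(summary, "event_summary"))
  measure <- match.arg(measure)
  arms <- unique(summary$arm)
  if (!reference %in% arms)
    stop_validation("reference arm \"%s\" not in summary (arms: %s)",
                    reference, paste(arms, collapse = ", "))
  active <- setdiff(arms, reference)
  rows <- list(); dropped <- character()
  for (lab in unique(summary$label)) {
    ref <- summary[summary$label == lab & summary$arm == reference, ]
    for (cmp in active) {
      trt <- summary[summary$label == lab & summary$arm == cmp, ]
      est <- tryCatch(
        effect_estimate(trt$n_participants, trt$arm_n,
                        ref$n_participants, ref$arm_n,
                        measure = measure, alpha = alpha,
                        correction = correction),
        harmvis_no_estimate = function(e) NULL)
      if (is.null(est)) {
        dropped <- c(dropped, lab)
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        label = lab, comparison = cmp, measure = measure,
        point = est$point, ci_low = est$ci_low, ci_high = est$ci_high,
        corrected = est$corrected, stringsAsFactors = FALSE)
    }
  }
  dropped <- unique(dropped)
  if (length(dropped))
    warning(sprintf("no events in either arm for: %s (dropped from estimates)",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), comparison = character(),
               measure = character(), point = numeric(), ci_low = numeric(),
               ci_high = numeric(), corrected = logical())
  attr(out, "dropped") <- dropped
  attr(out, "reference") <- reference
  attr(out, "alpha") <- alpha
  class(out) <- c("effect_table", "data.frame")
  out
}

#' Order effect estimates for the dot plot
#'
#' Descending by point estimate (highest risk at the top of the plot), ties
#' broken alphabetically by label. All estimates must share one measure.
#'
#' @param estimates an `effect_table` (or data frame with `label`, `point`,
#'   `measure`).
#' @return The input reordered; attributes (`dropped`, `reference`) are
#'   preserved.
#' @export
dot_plot_order <- function(estimates) {
  if (length(unique(estimates$measure)) > 1)
    stop_validation("estimates mix measures (%s): order is only defined within one measure",
                    paste(unique(estimates$measure), collapse = ", "))
  ord <- order(-estimates$point, estimates$label)
  out <- estimates[ord, , drop = FALSE]
  rownames(out) <- NULL
  for (at in c("dropped", "reference", "alpha"))
    attr(out, at) <- attr(estimates, at)
  class(out) <- class(estimates)
  out
}
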