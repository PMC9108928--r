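# Participant-level trial data container and per-participant derivations.
#
# A trial_dataset holds four tables:
#   roster        participant_id, arm, followup_days
#   events        participant_id, term, group, severity, onset_day
#   measurements  participant_id, outcome, visit_time, value
#   ranges        outcome, lower, upper, units
# plus an ordered severity scale. All statistics and figures consume this
# container; validation is total, with row-addressed error messages.

#' Default ordered severity scale
#' @export
default_severity_scale <- c("mild", "moderate", "severe")

empty_events <- function() {
  data.frame(participant_id = character(), term = character(),
             group = character(), severity = character(),
             onset_day = numeric(), stringsAsFactors = FALSE)
}

empty_measurements <- function() {
  data.frame(participant_id = character(), outcome = character(),
             visit_time = numeric(), value = numeric(),
             stringsAsFactors = FALSE)
}

empty_ranges <- function() {
  data.frame(outcome = character(), lower = numeric(), upper = numeric(),
             units = character(), stringsAsFactors = FALSE)
}

#' Assemble and validate a participant-level trial dataset
#'
#' @param roster data frame with columns `participant_id`, `arm`,
#'   `followup_days` (days from randomisation to end of observation; `t = 0`
#'   at randomisation).
#' @param events adverse-event records: `participant_id`, `term`, `group`
#'   (body system; missing values become `"Other"`), `severity` (a member of
#'   `severity_scale`), `onset_day`. Multiple records per participant and
#'   term are allowed (recurrent events).
#' @param measurements continuous outcome records: `participant_id`,
#'   `outcome`, `visit_time` (`0` denotes baseline), `value`.
#' @param ranges per-outcome normal limits: `outcome`, `lower`, `upper`,
#'   `units` (either limit may be `NA`).
#' @param severity_scale ordered character vector, least to most severe.
#'
#' @return An object of class `trial_dataset`.
#' @details Validation enforces: unique roster ids; non-negative follow-up;
#'   every event/measurement participant present in the roster; severities
#'   drawn from the scale; `onset_day` within the participant's follow-up;
#'   unique (participant, outcome, visit) measurement keys; `lower < upper`
#'   where both limits are present. Violations raise a
#'   `harmvis_validation_error` naming the offending row.
#' @export
trial_dataset <- function(roster, events = NULL, measurements = NULL,
                          ranges = NULL,
                          severity_scale = default_severity_scale) {
  roster <- as.data.frame(roster)
  events <- if (is.null(events) || !nrow(as.data.frame(events)))
    empty_events() else as.data.frame(events)
  measurements <- if (is.null(measurements) || !nrow(as.data.frame(measurements)))
    empty_measurements() else as.data.frame(measurements)
  ranges <- if (is.null(ranges) || !nrow(as.data.frame(ranges)))
    empty_ranges() else as.data.frame(ranges)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop_validation("%s table is missing column(s): %s", what,
                      paste(miss, collapse = ", "))
  }
  need(roster, c("participant_id", "arm", "followup_days"), "roster")
  need(events, c("participant_id", "term", "severity", "onset_day"), "events")
  need(measurements, c("participant_id", "outcome", "visit_time", "value"),
       "measurements")
  need(ranges, c("outcome", "lower", "upper"), "ranges")

  roster$participant_id <- as.character(roster$participant_id)
  roster$arm <- as.character(roster$arm)
  roster$followup_days <- as.numeric(roster$followup_days)

  if (!is.character(severity_scale) || length(severity_scale) < 1 ||
      anyDuplicated(severity_scale))
    stop_validation("severity_scale must be a character vector of distinct grades")

  dup <- which(duplicated(roster$participant_id))
  if (length(dup))
    stop_validation("roster row %d: duplicate participant_id \"%s\"",
                    dup[1], roster$participant_id[dup[1]])
  bad <- which(is.na(roster$followup_days) | roster$followup_days < 0)
  if (length(bad))
    stop_validation("roster row %d: followup_days must be a non-negative number",
                    bad[1])
  if (anyNA(roster$arm) || any(roster$arm == ""))
    stop_validation("roster row %d: missing arm label",
                    which(is.na(roster$arm) | roster$arm == "")[1])

  if (nrow(events)) {
    events$participant_id <- as.character(events$participant_id)
    events$term <- as.character(events$term)
    if (!"group" %in% names(events)) events$group <- NA_character_
    events$group <- as.character(events$group)
    events$group[is.na(events$group) | events$group == ""] <- "Other"
    events$severity <- as.character(events$severity)
    events$onset_day <- as.numeric(events$onset_day)

    unknown <- which(!events$participant_id %in% roster$participant_id)
    if (length(unknown))
      stop_validation("events row %d: participant \"%s\" is not in the roster",
                      unknown[1], events$participant_id[unknown[1]])
    badsev <- which(!events$severity %in% severity_scale)
    if (length(badsev))
      stop_validation(
        "events row %d: severity \"%s\" is not in the severity scale (%s)",
        badsev[1], events$severity[badsev[1]],
        paste(severity_scale, collapse = " < "))
    fup <- roster$followup_days[match(events$participant_id,
                                      roster$participant_id)]
    badonset <- which(is.na(events$onset_day) | events$onset_day < 0 |
                        events$onset_day > fup)
    if (length(badonset))
      stop_validation(
        "events row %d: onset_day %s outside participant \"%s\" follow-up [0, %s]",
        badonset[1], format(events$onset_day[badonset[1]]),
        events$participant_id[badonset[1]], format(fup[badonset[1]]))
  }

  if (nrow(measurements)) {
    measurements$participant_id <- as.character(measurements$participant_id)
    measurements$outcome <- as.character(measurements$outcome)
    measurements$visit_time <- as.numeric(measurements$visit_time)
    measurements$value <- as.numeric(measurements$value)
    unknown <- which(!measurements$participant_id %in% roster$participant_id)
    if (length(unknown))
      stop_validation(
        "measurements row %d: participant \"%s\" is not in the roster",
        unknown[1], measurements$participant_id[unknown[1]])
    key <- paste(measurements$participant_id, measurements$outcome,
                 measurements$visit_time)
    dup <- which(duplicated(key))
    if (length(dup))
      stop_validation(
        "measurements row %d: duplicate (participant, outcome, visit_time) key",
        dup[1])
  }

  if (nrow(ranges)) {
    ranges$outcome <- as.character(ranges$outcome)
    ranges$lower <- as.numeric(ranges$lower)
    ranges$upper <- as.numeric(ranges$upper)
    if (!"units" %in% names(ranges)) ranges$units <- NA_character_
    bad <- which(!is.na(ranges$lower) & !is.na(ranges$upper) &
                   ranges$lower >= ranges$upper)
    if (length(bad))
      stop_validation("ranges row %d: lower limit must be below upper limit",
                      bad[1])
  }

  structure(list(roster = roster[, c("participant_id", "arm", "followup_days")],
                 events = events[, c("participant_id", "term", "group",
                                     "severity", "onset_day"), drop = FALSE],
                 measurements = measurements[, c("participant_id", "outcome",
                                                 "visit_time", "value"),
                                             drop = FALSE],
                 ranges = ranges[, c("outcome", "lower", "upper", "units"),
                                 drop = FALSE],
                 severity_scale = severity_scale),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("<trial_dataset>\n")
  cat(sprintf("  participants : %d in %d arm(s) (%s)\n", nrow(x$roster),
              length(unique(x$roster$arm)),
              paste(unique(x$roster$arm), collapse = ", ")))
  cat(sprintf("  events       : %d record(s), %d term(s), %d group(s)\n",
              nrow(x$events), length(unique(x$events$term)),
              length(unique(x$events$group))))
  cat(sprintf("  measurements : %d record(s), %d outcome(s)\n",
              nrow(x$measurements), length(unique(x$measurements$outcome))))
  cat(sprintf("  severity     : %s\n", paste(x$severity_scale, collapse = " < ")))
  invisible(x)
}

#' Read a trial dataset from delimited text files
#'
#' Reads the four CSV tables (header row, UTF-8) and validates them into a
#' [trial_dataset()]. The severity scale and normal ranges may alternatively
#' be supplied through a YAML configuration file with top-level keys
#' `severity_scale` (list of grades, least to most severe) and `ranges`
#' (list of records with `outcome`, `lower`, `upper`, `units`).
#'
#' @param roster_path,events_path,measurements_path,ranges_path file paths;
#'   all but the roster may be `NULL`.
#' @param severity_scale ordered grades; overridden by `config`.
#' @param config optional YAML configuration file path.
#' @return A validated `trial_dataset`.
#' @export
read_trial <- function(roster_path, events_path = NULL,
                       measurements_path = NULL, ranges_path = NULL,
                       severity_scale = default_severity_scale,
                       config = NULL) {
  read1 <- function(p) if (is.null(p)) NULL else
    read.csv(p, stringsAsFactors = FALSE, check.names = FALSE)
  ranges <- read1(ranges_path)
  if (!is.null(config)) {
    cfg <- yaml::read_yaml(config)
    if (!is.null(cfg$severity_scale))
      severity_scale <- as.character(unlist(cfg$severity_scale))
    if (!is.null(cfg$ranges))
      ranges <- do.call(rbind, lapply(cfg$ranges, function(r)
        data.frame(outcome = r$outcome,
                   lower = r$lower %||% NA_real_,
                   upper = r$upper %||% NA_real_,
                   units = r$units %||% NA_character_)))
  }
  trial_dataset(roster = read1(roster_path), events = read1(events_path),
                measurements = read1(measurements_path), ranges = ranges,
                severity_scale = severity_scale)
}

#' Write a trial dataset to CSV files
#'
#' Writes `roster.csv`, `events.csv`, `measurements.csv` and `ranges.csv`
#' into `dir`. Inverse of [read_trial()] up to column classes.
#'
#' @param dataset a `trial_dataset`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_trial <- function(dataset, dir) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("roster.csv", "events.csv", "measurements.csv",
                            "ranges.csv"))
  write.csv(dataset$roster, paths[1], row.names = FALSE)
  write.csv(dataset$events, paths[2], row.names = FALSE)
  write.csv(dataset$measurements, paths[3], row.names = FALSE)
  write.csv(dataset$ranges, paths[4], row.names = FALSE)
  invisible(paths)
}

# -- selectors --------------------------------------------------------------

match_events <- function(dataset, selector) {
  ev <- dataset$events
  if (identical(selector, "any") || is.null(selector)) return(ev)
  hit <- ev$term == selector | ev$group == selector
  if (!selector %in% c(ev$term, ev$group))
    stop_validation(
      "selector \"%s\" matches no event term or group; available terms: %s; groups: %s",
      selector,
      paste(sort(unique(ev$term)), collapse = ", ") %|e|% "(none)",
      paste(sort(unique(ev$group)), collapse = ", ") %|e|% "(none)")
  ev[hit, , drop = FALSE]
}

`%|e|%` <- function(x, y) if (!nzchar(x)) y else x

#' Time to first event per participant
#'
#' For every roster participant, the earliest onset day of an event matching
#' `selector`, or the follow-up time with censored status when no event
#' matched. Events occurring on the censoring day count as events.
#'
#' @param dataset a `trial_dataset`.
#' @param selector an event term, a body-system group, or `"any"`.
#' @return Data frame with columns `participant_id`, `arm`, `time`,
#'   `status` (1 = event, 0 = censored); exactly one row per roster
#'   participant.
#' @export
first_event_times <- function(dataset, selector = "any") {
  stopifnot(inherits(dataset, "trial_dataset"))
  ev <- match_events(dataset, selector)
  out <- dataset$roster[, c("participant_id", "arm")]
  out$time <- dataset$roster$followup_days
  out$status <- 0L
  if (nrow(ev)) {
    first <- tapply(ev$onset_day, ev$participant_id, min)
    idx <- match(names(first), out$participant_id)
    out$time[idx] <- as.numeric(first)
    out$status[idx] <- 1L
  }
  rownames(out) <- NULL
  out
}

#' Recurrent event times per participant
#'
#' All matching event times joined with arm and follow-up, the input to
#' [mcf_estimate()].
#'
#' @inheritParams first_event_times
#' @return Data frame `participant_id`, `arm`, `time` (one row per event
#'   record); roster follow-up is attached as attribute `"followup"`
#'   (a data frame `participant_id`, `arm`, `followup_days`).
#' @export
recurrent_events <- function(dataset, selector = "any") {
  stopifnot(inherits(dataset, "trial_dataset"))
  ev <- match_events(dataset, selector)
  out <- data.frame(participant_id = ev$participant_id,
                    arm = dataset$roster$arm[match(ev$participant_id,
                                                   dataset$roster$participant_id)],
                    time = ev$onset_day, stringsAsFactors = FALSE)
  attr(out, "followup") <- dataset$roster
  out
}

#' Maximum severity per participant and event
#'
#' Each participant contributes at most one count per term (or group), at
#' the highest severity grade they recorded for it: a participant with a
#' mild and a moderate occurrence of the same event is counted once, as
#' moderate.
#'
#' @param dataset a `trial_dataset`.
#' @param by `"group"` (body system) or `"term"`.
#' @return Data frame `arm`, `label`, `severity`, `n` (participants), with
#'   `severity` an ordered factor on the dataset's scale and an `arm_n`
#'   column giving the roster denominator. Counts over grades within
#'   (arm, label) sum to the number of participants with at least one such
#'   event.
#' @export
max_severity <- function(dataset, by = c("group", "term")) {
  stopifnot(inherits(dataset, "trial_dataset"))
  by <- match.arg(by)
  ev <- dataset$events
  scale <- dataset$severity_scale
  arm_sizes <- table(dataset$roster$arm)
  if (!nrow(ev)) {
    out <- data.frame(arm = character(), label = character(),
                      severity = factor(character(), levels = scale,
                                        ordered = TRUE),
                      n = integer(), arm_n = integer())
    return(out)
  }
  ev$label <- ev[[by]]
  ev$rank <- match(ev$severity, scale)
  agg <- aggregate(rank ~ participant_id + label, data = ev, FUN = max)
  agg$arm <- dataset$roster$arm[match(agg$participant_id,
                                      dataset$roster$participant_id)]
  cnt <- aggregate(list(n = agg$participant_id),
                   by = list(arm = agg$arm, label = agg$label,
                             rank = agg$rank),
                   FUN = length)
  out <- data.frame(arm = cnt$arm, label = cnt$label,
                    severity = factor(scale[cnt$rank], levels = scale,
                                      ordered = TRUE),
                    n = cnt$n,
                    arm_n = as.integer(arm_sizes[cnt$arm]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$label, out$arm, out$severity), ]
  rownames(out) <- NULL
  out
}

#' Distribution of events per participant
#'
#' Tabulates, within each arm, how many participants experienced exactly
#' `k` matching events (k = 0 included), with percentages of the arm roster.
#'
#' @inheritParams first_event_times
#' @return Data frame `arm`, `k`, `n`, `pct`; percentages within an arm sum
#'   to 100.
#' @export
event_counts <- function(dataset, selector = "any") {
  stopifnot(inherits(dataset, "trial_dataset"))
  ev <- match_events(dataset, selector)
  roster <- dataset$roster
  k <- integer(nrow(roster))
  if (nrow(ev)) {
    tab <- table(ev$participant_id)
    idx <- match(names(tab), roster$participant_id)
    k[idx] <- as.integer(tab)
  }
  cnt <- aggregate(list(n = roster$participant_id),
                   by = list(arm = roster$arm, k = k), FUN = length)
  cnt <- cnt[order(cnt$arm, cnt$k), ]
  arm_sizes <- table(roster$arm)
  cnt$pct <- 100 * cnt$n / as.numeric(arm_sizes[cnt$arm])
  rownames(cnt) <- NULL
  cnt
}

#' Baseline and maximum post-baseline value per participant
#'
#' @param dataset a `trial_dataset`.
#' @param outcome a measurement outcome name.
#' @return Data frame `participant_id`, `arm`, `baseline`, `maximum` for
#'   participants having both a baseline (`visit_time == 0`) and at least
#'   one post-baseline value. Participants missing either are reported in
#'   attribute `"excluded"` (`participant_id`, `reason`).
#' @export
baseline_max <- function(dataset, outcome) {
  stopifnot(inherits(dataset, "trial_dataset"))
  m <- dataset$measurements
  if (!outcome %in% m$outcome)
    stop_validation("outcome \"%s\" not found; available: %s", outcome,
                    paste(sort(unique(m$outcome)), collapse = ", "))
  m <- m[m$outcome == outcome, , drop = FALSE]
  roster <- dataset$roster
  rows <- lapply(roster$participant_id, function(id) {
    mi <- m[m$participant_id == id, , drop = FALSE]
    base <- mi$value[mi$visit_time == 0]
    post <- mi$value[mi$visit_time > 0]
    if (!nrow(mi))
      return(list(excl = "no measurements"))
    if (!length(base)) return(list(excl = "no baseline"))
    if (!length(post)) return(list(excl = "no post-baseline"))
    list(row = data.frame(participant_id = id,
                          arm = roster$arm[roster$participant_id == id],
                          baseline = base[1], maximum = max(post),
                          stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  if (is.null(out))
    out <- data.frame(participant_id = character(), arm = character(),
                      baseline = numeric(), maximum = numeric())
  excl_idx <- vapply(rows, function(r) !is.null(r$excl), logical(1))
  attr(out, "excluded") <- data.frame(
    participant_id = roster$participant_id[excl_idx],
    reason = vapply(rows[excl_idx], `[[`, character(1), "excl"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
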