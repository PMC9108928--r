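# Synthetic two-arm trial generator with controlled ground truth, used
# throughout the test-suite in place of restricted-access trial data.
# Recurrent adverse events follow homogeneous Poisson processes with
# arm-specific rates; dropout is an independent exponential hazard
# (non-informative censoring); laboratory trajectories are Gaussian with
# arm-by-visit mean shifts. One master seed drives independent substreams
# per component, so adding a lab outcome does not perturb the event draws.

#' Define a simulated adverse-event group
#'
#' @param label body-system label.
#' @param rate named numeric: recurrent-event rate per participant-year by
#'   arm (a homogeneous Poisson intensity over each participant's observed
#'   window).
#' @param p_any named numeric in \[0, 1\]: probability a participant is
#'   susceptible to the group at all (a simple frailty; default 1 for all
#'   arms). Non-susceptible participants record no events.
#' @param severity_mix named numeric mixture over the severity scale,
#'   summing to 1; each event's grade is drawn independently from it.
#' @param term event term; defaults to the label.
#' @return A `sim_group` list.
#' @export
sim_group <- function(label, rate, p_any = NULL,
                      severity_mix = c(mild = 0.6, moderate = 0.3,
                                       severe = 0.1),
                      term = label) {
  if (any(rate < 0)) stop_validation("rates must be non-negative")
  if (abs(sum(severity_mix) - 1) > 1e-8)
    stop_validation("severity_mix must sum to 1 (group \"%s\")", label)
  if (!is.null(p_any) && any(p_any < 0 | p_any > 1))
    stop_validation("p_any must lie in [0, 1] (group \"%s\")", label)
  structure(list(label = label, term = term, rate = rate, p_any = p_any,
                 severity_mix = severity_mix), class = "sim_group")
}

#' Define a simulated laboratory outcome
#'
#' Values are `baseline_i + effect[arm, visit] + residual noise`, where
#' `baseline_i ~ N(baseline_mean, baseline_sd)` is a participant-level
#' intercept.
#'
#' @param name outcome name.
#' @param baseline_mean,baseline_sd baseline distribution.
#' @param effect named list: per arm, a numeric vector of mean shifts at
#'   each post-baseline visit (recycled if shorter than the schedule).
#' @param residual_sd within-participant noise SD.
#' @param lower,upper normal-range limits (either may be `NA`).
#' @param units unit label.
#' @param visits visit schedule in days, starting at 0 (baseline).
#' @return A `sim_lab` list.
#' @export
sim_lab <- function(name, baseline_mean, baseline_sd, effect, residual_sd,
                    lower = NA, upper = NA, units = "",
                    visits = c(0, 14, 28, 56, 84)) {
  if (baseline_sd < 0 || residual_sd < 0)
    stop_validation("standard deviations must be non-negative")
  if (visits[1] != 0) stop_validation("visit schedule must start at baseline 0")
  structure(list(name = name, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, effect = effect,
                 residual_sd = residual_sd, lower = lower, upper = upper,
                 units = units, visits = visits), class = "sim_lab")
}

#' Simulation configuration
#'
#' @param arms named integer vector of arm sizes, e.g.
#'   `c(placebo = 300, intervention = 300)`.
#' @param groups list of [sim_group()] definitions.
#' @param followup_days administrative follow-up.
#' @param dropout_rate per-year exponential dropout hazard (0 = none),
#'   independent of events.
#' @param labs list of [sim_lab()] definitions.
#' @param severity_scale ordered grades.
#' @param seed master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(arms, groups = list(), followup_days = 365,
                       dropout_rate = 0, labs = list(),
                       severity_scale = default_severity_scale, seed = 1) {
  if (is.null(names(arms)) || any(!nzchar(names(arms))))
    stop_validation("arms must be a named vector of sizes")
  if (any(arms < 1)) stop_validation("arm sizes must be >= 1")
  if (followup_days <= 0) stop_validation("followup_days must be positive")
  if (dropout_rate < 0) stop_validation("dropout_rate must be non-negative")
  for (g in groups) {
    if (!inherits(g, "sim_group")) stop_validation("groups must be sim_group objects")
    if (!all(names(arms) %in% names(g$rate)))
      stop_validation("group \"%s\" lacks a rate for every arm", g$label)
    if (!all(names(g$severity_mix) %in% severity_scale))
      stop_validation("group \"%s\" severity_mix uses grades outside the scale",
                      g$label)
  }
  for (l in labs)
    if (!inherits(l, "sim_lab")) stop_validation("labs must be sim_lab objects")
  structure(list(arms = arms, groups = groups, followup_days = followup_days,
                 dropout_rate = dropout_rate, labs = labs,
                 severity_scale = severity_scale, seed = seed),
            class = "sim_config")
}

#' Default two-arm study conditions
#'
#' A placebo-controlled parallel trial of 300 participants per arm followed
#' for one year with 10%/year non-informative dropout. Six body systems
#' have arm-specific recurrent-event rates spanning common (infections,
#' around one event per participant-year) to rare (renal and urinary)
#' events, with mild-dominated severity mixtures; one eosinophil-like
#' laboratory outcome falls sharply under the intervention while placebo
#' stays near its (elevated) baseline.
#'
#' @param seed master seed.
#' @return A `sim_config`.
#' @export
default_sim_config <- function(seed = 1) {
  arms <- c(placebo = 300, intervention = 300)
  groups <- list(
    sim_group("infections and infestations",
              rate = c(placebo = 1.6, intervention = 1.1),
              severity_mix = c(mild = 0.55, moderate = 0.35, severe = 0.10)),
    sim_group("gastrointestinal disorders",
              rate = c(placebo = 1.0, intervention = 0.6),
              severity_mix = c(mild = 0.6, moderate = 0.3, severe = 0.1)),
    sim_group("blood and lymphatic system disorders",
              rate = c(placebo = 0.8, intervention = 0.5),
              severity_mix = c(mild = 0.7, moderate = 0.2, severe = 0.1)),
    sim_group("respiratory disorders",
              rate = c(placebo = 0.35, intervention = 0.45),
              severity_mix = c(mild = 0.6, moderate = 0.3, severe = 0.1)),
    sim_group("renal and urinary disorders",
              rate = c(placebo = 0.12, intervention = 0.08),
              severity_mix = c(mild = 0.5, moderate = 0.4, severe = 0.1)),
    sim_group("Other",
              rate = c(placebo = 0.3, intervention = 0.45),
              severity_mix = c(mild = 0.3, moderate = 0.4, severe = 0.3)))
  labs <- list(
    sim_lab("eosinophil count", baseline_mean = 0.55, baseline_sd = 0.25,
            effect = list(placebo = c(0, 0, 0, 0),
                          intervention = c(-0.35, -0.4, -0.42, -0.42)),
            residual_sd = 0.1, lower = 0.02, upper = 0.4,
            units = "10^9/L", visits = c(0, 14, 28, 56, 84)))
  sim_config(arms = arms, groups = groups, followup_days = 365,
             dropout_rate = 0.1, labs = labs, seed = seed)
}

# deterministic substream seed from the master seed and a component tag
substream <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629) + 1L
}

#' Simulate a trial dataset
#'
#' Generates a [trial_dataset()] from a [sim_config()]: dropout times are
#' exponential (truncated at administrative follow-up); for each group and
#' susceptible participant, event counts are Poisson at the arm's rate over
#' the observed window with onset days uniform within it; severities are
#' drawn from the group's mixture; laboratory values follow the arm-visit
#' mean structure with Gaussian noise. Fully reproducible from the config
#' seed.
#'
#' @param config a `sim_config`.
#' @return A validated `trial_dataset`.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  arms <- config$arms
  ids <- unlist(lapply(names(arms), function(a)
    sprintf("%s-%03d", toupper(substr(a, 1, 3)), seq_len(arms[[a]]))),
    use.names = FALSE)
  arm_of <- rep(names(arms), times = arms)

  # dropout / follow-up
  set.seed(substream(config$seed, "dropout"))
  fup <- rep(config$followup_days, length(ids))
  if (config$dropout_rate > 0) {
    drop_day <- rexp(length(ids), rate = config$dropout_rate / 365)
    fup <- pmin(fup, ceiling(drop_day))
  }
  roster <- data.frame(participant_id = ids, arm = arm_of,
                       followup_days = fup, stringsAsFactors = FALSE)

  # recurrent events per group
  ev <- list()
  for (g in config$groups) {
    set.seed(substream(config$seed, paste0("events:", g$label)))
    p_any <- if (is.null(g$p_any)) setNames(rep(1, length(arms)), names(arms))
             else g$p_any
    susceptible <- rbinom(length(ids), 1, p_any[arm_of]) == 1
    lambda <- g$rate[arm_of] * fup / 365
    counts <- ifelse(susceptible, rpois(length(ids), lambda), 0L)
    tot <- sum(counts)
    if (!tot) next
    pid <- rep(ids, counts)
    pfup <- rep(fup, counts)
    onset <- floor(runif(tot) * pfup)          # uniform day in [0, fup)
    sev <- sample(names(g$severity_mix), tot, replace = TRUE,
                  prob = g$severity_mix)
    ev[[length(ev) + 1]] <- data.frame(
      participant_id = pid, term = g$term, group = g$label, severity = sev,
      onset_day = onset, stringsAsFactors = FALSE)
  }
  events <- if (length(ev)) do.call(rbind, ev) else NULL

  # laboratory trajectories
  ms <- list(); rg <- list()
  for (l in config$labs) {
    set.seed(substream(config$seed, paste0("lab:", l$name)))
    base <- rnorm(length(ids), l$baseline_mean, l$baseline_sd)
    for (j in seq_along(l$visits)) {
      vt <- l$visits[j]
      shift <- if (j == 1) rep(0, length(ids)) else
        vapply(arm_of, function(a) {
          e <- l$effect[[a]] %||% 0
          e[min(j - 1, length(e))]
        }, numeric(1))
      val <- base + shift + rnorm(length(ids), 0, l$residual_sd)
      keep <- vt <= fup | vt == 0   # visits after dropout are missed
      ms[[length(ms) + 1]] <- data.frame(
        participant_id = ids[keep], outcome = l$name, visit_time = vt,
        value = val[keep], stringsAsFactors = FALSE)
    }
    rg[[length(rg) + 1]] <- data.frame(outcome = l$name, lower = l$lower,
                                       upper = l$upper, units = l$units,
                                       stringsAsFactors = FALSE)
  }
  trial_dataset(roster = roster, events = events,
                measurements = if (length(ms)) do.call(rbind, ms) else NULL,
                ranges = if (length(rg)) do.call(rbind, rg) else NULL,
                severity_scale = config$severity_scale)
}

#' A fixed, hand-enumerable eight-participant dataset
#'
#' Two arms (A, B) of four participants, used throughout the test-suite so
#' every derived statistic can be verified by hand. The records are:
#'
#' | id | arm | follow-up | events (term/group, severity, day) |
#' |----|-----|-----------|------------------------------------|
#' | A1 | A | 20 | headache (nervous, mild, 5); headache (nervous, moderate, 12) |
#' | A2 | A | 30 | nausea (gastro, severe, 10) |
#' | A3 | A | 30 | none |
#' | A4 | A | 15 | rash (skin, mild, 3) |
#' | B1 | B | 30 | headache (nervous, mild, 8) |
#' | B2 | B | 30 | nausea (gastro, mild, 4); nausea (gastro, mild, 9); rash (skin, moderate, 20) |
#' | B3 | B | 25 | none |
#' | B4 | B | 30 | none |
#'
#' Each participant also has an `eosinophil count` measurement at visits
#' 0, 10 and 20 (normal range 0.1-0.5), with simple values chosen so
#' baseline/maximum derivations are obvious.
#'
#' @return A validated `trial_dataset`.
#' @export
fixture_small <- function() {
  roster <- data.frame(
    participant_id = c("A1", "A2", "A3", "A4", "B1", "B2", "B3", "B4"),
    arm = rep(c("A", "B"), each = 4),
    followup_days = c(20, 30, 30, 15, 30, 30, 25, 30))
  events <- data.frame(
    participant_id = c("A1", "A1", "A2", "A4", "B1", "B2", "B2", "B2"),
    term = c("headache", "headache", "nausea", "rash", "headache",
             "nausea", "nausea", "rash"),
    group = c("nervous", "nervous", "gastro", "skin", "nervous",
              "gastro", "gastro", "skin"),
    severity = c("mild", "moderate", "severe", "mild", "mild",
                 "mild", "mild", "moderate"),
    onset_day = c(5, 12, 10, 3, 8, 4, 9, 20))
  ids <- roster$participant_id
  measurements <- data.frame(
    participant_id = rep(ids, each = 3),
    outcome = "eosinophil count",
    visit_time = rep(c(0, 10, 20), times = 8),
    value = c(0.30, 0.45, 0.40,   # A1
              0.50, 0.60, 0.55,   # A2
              0.20, 0.25, 0.20,   # A3
              0.35, 0.30, 0.30,   # A4
              0.40, 0.55, 0.60,   # B1
              0.25, 0.35, 0.30,   # B2
              0.45, 0.50, 0.65,   # B3
              0.30, 0.30, 0.30))  # B4
  ranges <- data.frame(outcome = "eosinophil count", lower = 0.1,
                       upper = 0.5, units = "10^9/L")
  trial_dataset(roster, events, measurements, ranges)
}
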