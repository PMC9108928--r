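# Independent brute-force oracles, written as explicit loops over raw
# records. They deliberately share no code with the package internals.

oracle_km <- function(time, status) {
  et <- sort(unique(time[status == 1]))
  s <- 1
  out <- data.frame(time = numeric(), n_risk = numeric(),
                    n_event = numeric(), estimate = numeric())
  for (t in et) {
    at_risk <- 0
    deaths <- 0
    for (i in seq_along(time)) {
      if (time[i] >= t) at_risk <- at_risk + 1
      if (time[i] == t && status[i] == 1) deaths <- deaths + 1
    }
    s <- s * (1 - deaths / at_risk)
    out <- rbind(out, data.frame(time = t, n_risk = at_risk,
                                 n_event = deaths, estimate = s))
  }
  out
}

oracle_mcf <- function(event_df, followup) {
  et <- sort(unique(event_df$time))
  m <- 0
  out <- data.frame(time = numeric(), estimate = numeric())
  for (t in et) {
    under_obs <- 0
    for (f in followup) if (f >= t) under_obs <- under_obs + 1
    d <- 0
    for (i in seq_len(nrow(event_df)))
      if (event_df$time[i] == t) d <- d + 1
    m <- m + d / under_obs
    out <- rbind(out, data.frame(time = t, estimate = m))
  }
  out
}

oracle_event_summary <- function(dataset, by) {
  roster <- dataset$roster
  ev <- dataset$events
  out <- data.frame()
  for (lab in sort(unique(ev[[by]]))) {
    for (a in sort(unique(roster$arm))) {
      ids_in_arm <- roster$participant_id[roster$arm == a]
      with_event <- character()
      n_events <- 0
      for (i in seq_len(nrow(ev))) {
        if (ev[[by]][i] == lab && ev$participant_id[i] %in% ids_in_arm) {
          with_event <- union(with_event, ev$participant_id[i])
          n_events <- n_events + 1
        }
      }
      out <- rbind(out, data.frame(
        label = lab, arm = a, arm_n = length(ids_in_arm),
        n_participants = length(with_event), n_events = n_events,
        pct = 100 * length(with_event) / length(ids_in_arm)))
    }
  }
  out
}

oracle_event_counts <- function(dataset, selector = "any") {
  roster <- dataset$roster
  ev <- dataset$events
  if (!identical(selector, "any"))
    ev <- ev[ev$term == selector | ev$group == selector, , drop = FALSE]
  out <- data.frame()
  for (a in sort(unique(roster$arm))) {
    ids <- roster$participant_id[roster$arm == a]
    kk <- integer(length(ids))
    for (j in seq_along(ids))
      kk[j] <- sum(ev$participant_id == ids[j])
    for (k in sort(unique(kk)))
      out <- rbind(out, data.frame(arm = a, k = k, n = sum(kk == k),
                                   pct = 100 * sum(kk == k) / length(ids)))
  }
  out
}

oracle_mean_sd <- function(dataset, outcome) {
  m <- dataset$measurements[dataset$measurements$outcome == outcome, ]
  roster <- dataset$roster
  out <- data.frame()
  for (a in sort(unique(roster$arm))) {
    ids <- roster$participant_id[roster$arm == a]
    sub <- m[m$participant_id %in% ids, ]
    for (vt in sort(unique(sub$visit_time))) {
      v <- sub$value[sub$visit_time == vt]
      mu <- sum(v) / length(v)
      s <- if (length(v) > 1) sqrt(sum((v - mu)^2) / (length(v) - 1)) else 0
      out <- rbind(out, data.frame(arm = a, visit_time = vt, n = length(v),
                                   center = mu, spread_low = mu - s,
                                   spread_high = mu + s))
    }
  }
  out
}
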