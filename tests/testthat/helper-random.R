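# Small random trial datasets (n <= 12) for oracle-equivalence and
# property checks. Integer times force ties so the tie conventions are
# exercised.

random_small_dataset <- function(n = NULL) {
  if (is.null(n)) n <- sample(4:12, 1)
  ids <- sprintf("P%02d", seq_len(n))
  arm <- sample(c("ctrl", "trt"), n, replace = TRUE)
  arm[1] <- "ctrl"; arm[2] <- "trt"   # both arms always present
  fup <- sample(5:30, n, replace = TRUE)
  roster <- data.frame(participant_id = ids, arm = arm, followup_days = fup)
  terms <- c("headache", "nausea", "rash")
  groups <- c(headache = "nervous", nausea = "gastro", rash = "skin")
  ev <- list()
  for (i in seq_len(n)) {
    k <- sample(0:3, 1)
    if (!k) next
    tm <- sample(terms, k, replace = TRUE)
    ev[[length(ev) + 1]] <- data.frame(
      participant_id = ids[i], term = tm, group = unname(groups[tm]),
      severity = sample(c("mild", "moderate", "severe"), k, replace = TRUE),
      onset_day = sample(0:fup[i], k, replace = TRUE))
  }
  meas <- data.frame(
    participant_id = rep(ids, each = 3),
    outcome = "lab", visit_time = rep(c(0, 7, 14), n),
    value = round(rnorm(3 * n, 10, 2), 2))
  trial_dataset(roster, if (length(ev)) do.call(rbind, ev) else NULL, meas,
                data.frame(outcome = "lab", lower = 6, upper = 14,
                           units = "U"))
}

random_records <- function(n = NULL) {
  if (is.null(n)) n <- sample(3:12, 1)
  data.frame(time = sample(1:8, n, replace = TRUE),
             status = sample(0:1, n, replace = TRUE))
}
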