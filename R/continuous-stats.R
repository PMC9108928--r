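# Longitudinal and distributional summaries for continuous harm outcomes:
# per-visit location/spread (for line graphs and violins), kernel density
# estimation (violin and density plots), and change scores from baseline.

#' Per-visit summary of a continuous outcome
#'
#' One summary per (arm, visit time): the sample size, a centre (mean or
#' median) and a spread interval (mean +/- SD, displaying the variability of
#' raw values rather than the precision of the mean, or Q1-Q3). Quantiles
#' use linear interpolation of order statistics (type 7), the R default,
#' fixed for reproducibility. Model-based summaries (e.g. mixed-model means
#' with confidence limits) are accepted by the line graph as pre-computed
#' rows of the same shape with `statistic = "model_ci"`; they are not
#' fitted here.
#'
#' @param dataset a `trial_dataset`.
#' @param outcome outcome name.
#' @param statistic `"mean_sd"` or `"median_iqr"`.
#' @return Data frame of class `timepoint_summary`: `arm`, `visit_time`,
#'   `n`, `center`, `spread_low`, `spread_high`, `statistic`.
#' @export
timepoint_summary <- function(dataset, outcome,
                              statistic = c("mean_sd", "median_iqr")) {
  stopifnot(inherits(dataset, "trial_dataset"))
  statistic <- match.arg(statistic)
  m <- dataset$measurements
  if (!outcome %in% m$outcome)
    stop_validation("outcome \"%s\" not found; available: %s", outcome,
                    paste(sort(unique(m$outcome)), collapse = ", "))
  m <- m[m$outcome == outcome, , drop = FALSE]
  m$arm <- dataset$roster$arm[match(m$participant_id,
                                    dataset$roster$participant_id)]
  keys <- unique(m[, c("arm", "visit_time")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    v <- m$value[m$arm == keys$arm[i] & m$visit_time == keys$visit_time[i]]
    if (statistic == "mean_sd") {
      ctr <- mean(v)
      sp <- if (length(v) > 1) sd(v) else 0
      lo <- ctr - sp; hi <- ctr + sp
    } else {
      ctr <- median(v)
      q <- quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
      lo <- q[1]; hi <- q[2]
    }
    data.frame(arm = keys$arm[i], visit_time = keys$visit_time[i],
               n = length(v), center = ctr, spread_low = lo,
               spread_high = hi, statistic = statistic,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$arm, out$visit_time), ]
  rownames(out) <- NULL
  class(out) <- c("timepoint_summary", "data.frame")
  out
}

#' Gaussian kernel density estimate
#'
#' Density of a continuous sample on a regular grid spanning the data plus
#' three bandwidths each side. The default bandwidth is Silverman's rule,
#' `0.9 * min(SD, IQR/1.34) * n^(-1/5)`; when the IQR is zero (heavily
#' tied data) the SD alone is used. No boundary correction is applied, so
#' for non-negative outcomes such as cell counts the estimate can extend
#' below zero -- a known display limitation users should weigh.
#'
#' @param values numeric sample with at least 2 distinct values.
#' @param bandwidth positive number, or `NULL` for Silverman's rule.
#' @param n_grid grid resolution.
#' @return List of class `kde_estimate`: `grid`, `density`, `bandwidth`.
#'   The trapezoid integral of `density` over `grid` is 1 (+/- 0.01).
#' @export
kde_estimate <- function(values, bandwidth = NULL, n_grid = 512) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < 2)
    stop_validation(
      "all values identical: a density is undefined; use a rug or point display")
  if (is.null(bandwidth)) {
    n <- length(values)
    iqr <- diff(quantile(values, c(0.25, 0.75), names = FALSE, type = 7))
    s <- sd(values)
    spread <- if (iqr > 0) min(s, iqr / 1.34) else s
    bandwidth <- 0.9 * spread * n^(-1 / 5)
  }
  if (bandwidth <= 0) stop_validation("bandwidth must be positive")
  d <- density(values, bw = bandwidth, kernel = "gaussian", cut = 3,
               n = n_grid)
  structure(list(grid = d$x, density = d$y, bandwidth = bandwidth),
            class = "kde_estimate")
}

#' @export
print.kde_estimate <- function(x, ...) {
  cat(sprintf("<kde_estimate> bandwidth %.4g, grid [%.4g, %.4g] x %d\n",
              x$bandwidth, min(x$grid), max(x$grid), length(x$grid)))
  invisible(x)
}

#' Change scores from baseline
#'
#' Per-participant change in a continuous outcome, either to a specific
#' visit time or to the maximum post-baseline value over the whole trial.
#' "Post-baseline" means every visit with `visit_time > 0`; if treatment
#' stopped before the last visit the later values are still included (the
#' convention is documented rather than configurable).
#'
#' @param dataset a `trial_dataset`.
#' @param outcome outcome name.
#' @param mode `"to_maximum"` or `"to_time"`.
#' @param time target visit time, required for `mode = "to_time"`.
#' @return Data frame `participant_id`, `arm`, `baseline`, `value`,
#'   `score` (`value - baseline`); participants lacking a baseline or the
#'   target value are reported in attribute `"excluded"`.
#' @export
change_scores <- function(dataset, outcome, mode = c("to_maximum", "to_time"),
                          time = NULL) {
  stopifnot(inherits(dataset, "trial_dataset"))
  mode <- match.arg(mode)
  if (mode == "to_time" && is.null(time))
    stop_validation("mode \"to_time\" needs a target `time`")
  m <- dataset$measurements
  if (!outcome %in% m$outcome)
    stop_validation("outcome \"%s\" not found; available: %s", outcome,
                    paste(sort(unique(m$outcome)), collapse = ", "))
  if (!any(m$outcome == outcome & m$visit_time == 0))
    stop_validation("outcome \"%s\" has no baseline (visit_time = 0) records",
                    outcome)
  m <- m[m$outcome == outcome, , drop = FALSE]
  roster <- dataset$roster
  rows <- lapply(roster$participant_id, function(id) {
    mi <- m[m$participant_id == id, , drop = FALSE]
    base <- mi$value[mi$visit_time == 0]
    if (!length(base)) return(list(excl = "no baseline"))
    if (mode == "to_maximum") {
      post <- mi$value[mi$visit_time > 0]
      if (!length(post)) return(list(excl = "no post-baseline"))
      val <- max(post)
    } else {
      val <- mi$value[mi$visit_time == time]
      if (!length(val))
        return(list(excl = sprintf("no value at time %s", format(time))))
      val <- val[1]
    }
    list(row = data.frame(participant_id = id,
                          arm = roster$arm[roster$participant_id == id],
                          baseline = base[1], value = val,
                          score = val - base[1], stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  if (is.null(out))
    out <- data.frame(participant_id = character(), arm = character(),
                      baseline = numeric(), value = numeric(),
                      score = numeric())
  excl_idx <- vapply(rows, function(r) !is.null(r$excl), logical(1))
  attr(out, "excluded") <- data.frame(
    participant_id = roster$participant_id[excl_idx],
    reason = vapply(rows[excl_idx], `[[`, character(1), "excl"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
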