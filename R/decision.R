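# Executable decision tree recommending endorsed plots from outcome
# characteristics. The mapping reproduces the consensus summary table of
# outcome characteristics (binary / count / continuous / time-to-event,
# single vs multiple outcomes, severity interest, recurrence, repeated
# measurement, distribution shape).

#' The ten endorsed plot names
#' @return Character vector of the endorsed visualisation names.
#' @export
endorsed_plots <- function() {
  c("dot plot", "stacked bar chart", "bar chart", "kaplan-meier plot",
    "survival ratio plot", "mean cumulative function plot", "line graph",
    "violin plot", "kernel density plot", "scatterplot matrix")
}

#' Recommend endorsed plots from outcome characteristics
#'
#' Maps the characteristics of the harm outcome(s) to be displayed onto
#' the endorsed visualisations. The recommendation is advisory: the trial
#' team must ultimately decide the most appropriate visualisations for
#' their data and objectives, and should continue to examine crude
#' numbers alongside any plot.
#'
#' @param outcome_type `"binary"`, `"count"`, `"continuous"` or
#'   `"time_to_event"`.
#' @param multiplicity `"single"` (one event/outcome of interest) or
#'   `"multiple"` (summarising the whole harm profile).
#' @param severity_of_interest is the severity grading of events part of
#'   the message? (binary outcomes only)
#' @param recurrent are repeat occurrences per participant of interest?
#'   Only meaningful for binary, count and time-to-event outcomes.
#' @param time_structure for continuous outcomes: `"repeated"` visits or a
#'   `"single_timepoint"`.
#' @param distribution_normalish for continuous outcomes: is the outcome
#'   roughly normal, with no particular interest in distribution shape?
#' @return List of class `plot_recommendation` with elements `plots`
#'   (character, possibly empty) and `note`.
#' @examples
#' recommend_plot("binary", "multiple")
#' recommend_plot("time_to_event", "single", recurrent = TRUE)
#' recommend_plot("time_to_event", "multiple")  # no suitable plot
#' @export
recommend_plot <- function(outcome_type = c("binary", "count", "continuous",
                                            "time_to_event"),
                           multiplicity = c("single", "multiple"),
                           severity_of_interest = FALSE,
                           recurrent = FALSE,
                           time_structure = c("repeated", "single_timepoint"),
                           distribution_normalish = TRUE) {
  outcome_type <- match.arg(outcome_type)
  multiplicity <- match.arg(multiplicity)
  time_structure <- match.arg(time_structure)
  if (recurrent && outcome_type == "continuous")
    stop_validation("`recurrent` is only meaningful for binary, count or time-to-event outcomes")

  rec <- function(plots, note) structure(list(plots = plots, note = note),
                                         class = "plot_recommendation")
  if (outcome_type == "binary") {
    if (multiplicity == "multiple" && severity_of_interest)
      return(rec("stacked bar chart",
                 "Shows occurrence and maximum severity of multiple events; most severe segment drawn closest to the axis."))
    if (multiplicity == "multiple")
      return(rec("dot plot",
                 "Comprehensive summary of multiple binary events: absolute risks, a comparative estimate with confidence intervals, and the data table."))
    return(rec("bar chart",
               "Percentage of participants by number of events experienced, per arm; suits single or aggregated binary events."))
  }
  if (outcome_type == "count")
    return(rec("bar chart",
               "Distribution of event counts per participant by arm; applies to recurrent count outcomes regardless of multiplicity."))
  if (outcome_type == "time_to_event") {
    if (multiplicity == "multiple")
      return(rec(character(),
                 "No suitable plot: no endorsed visualisation displays multiple time-to-event outcomes simultaneously; consider separate plots per event."))
    if (recurrent)
      return(rec("mean cumulative function plot",
                 "Mean cumulative number of events per participant over time; the endorsed display for recurrent events."))
    return(rec(c("kaplan-meier plot", "survival ratio plot"),
               "Kaplan-Meier with extended at-risk table for within-arm estimates; survival ratio plot alongside it for the direct between-arm comparison."))
  }
  # continuous
  if (multiplicity == "multiple")
    return(rec("scatterplot matrix",
               "Exploratory display of baseline versus maximum values across outcomes, with normal-limit quadrants and labelled outliers."))
  if (time_structure == "single_timepoint")
    return(rec("kernel density plot",
               "Distribution of the outcome (or a change score) at one time point, compared informally between arms."))
  if (!distribution_normalish)
    return(rec("violin plot",
               "Shows the full distribution over visits; an alternative to the line graph when the outcome is far from normal or the distribution itself is of interest. Line graph remains an option for model-based summaries."))
  rec("line graph",
      "Centre and spread per visit against normal limits; the violin plot is the endorsed alternative when distribution shape matters.")
}

#' @export
print.plot_recommendation <- function(x, ...) {
  if (length(x$plots))
    cat("Recommended plot(s):", paste(x$plots, collapse = "; "), "\n")
  else cat("Recommended plot(s): none\n")
  cat("Note:", x$note, "\n")
  invisible(x)
}
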