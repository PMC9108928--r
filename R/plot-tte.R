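# Time-to-event displays: Kaplan-Meier plot with extended at-risk tables,
# mean cumulative function plot, and the survival ratio plot with its
# signal-indicator bar.

# step-expand a survival_curve for drawing: prepend the boundary value at
# t = 0 and extend the last value to max follow-up
curve_draw_data <- function(curve, arm) {
  init <- if (attr(curve, "kind") == "km") 1 else 0
  df <- as.data.frame(curve)[, c("time", "estimate", "ci_low", "ci_high")]
  first <- data.frame(time = 0, estimate = init, ci_low = init,
                      ci_high = init)
  last <- if (nrow(df)) df[nrow(df), , drop = FALSE] else first
  last$time <- max(attr(curve, "max_time") %||% last$time, last$time)
  out <- rbind(first, df, last)
  out$arm <- arm
  out
}

as_curve_list <- function(curves) {
  if (inherits(curves, "survival_curve"))
    curves <- setNames(list(curves), attr(curves, "arm") %||% "arm 1")
  if (is.null(names(curves)))
    names(curves) <- vapply(seq_along(curves), function(i)
      attr(curves[[i]], "arm") %||% paste("arm", i), character(1))
  curves
}

risk_table_panel <- function(rt, arms, styles) {
  long <- do.call(rbind, lapply(c("n_risk", "cum_censored", "cum_events"),
                                function(col)
    data.frame(arm = rt$arm, time = rt$time, metric = col,
               value = rt[[col]], stringsAsFactors = FALSE)))
  metric_lab <- c(n_risk = "At risk", cum_censored = "Censored",
                  cum_events = "Events")
  long$rowlab <- paste(long$arm, metric_lab[long$metric], sep = ": ")
  rows <- as.vector(t(outer(arms, metric_lab, paste, sep = ": ")))
  long$rowlab <- factor(long$rowlab, levels = rev(rows))
  ggplot(long, aes(x = .data$time, y = .data$rowlab,
                   label = .data$value)) +
    geom_text(size = 2.6) +
    labs(x = NULL, y = NULL) +
    theme_minimal(base_size = 9) +
    theme(panel.grid = element_blank(), axis.text.x = element_blank())
}

tte_figure <- function(kind, curves, rtab, bands, grayscale, reversed_axis,
                       ylab) {
  curves <- as_curve_list(curves)
  arms <- names(curves)
  if (!is.null(rtab)) {
    if (!inherits(rtab, "risk_table"))
      stop_validation("risk_table must come from risk_table()")
    if (!setequal(unique(rtab$arm), arms))
      stop_validation("risk table arms (%s) do not match curve arms (%s)",
                      paste(sort(unique(rtab$arm)), collapse = ", "),
                      paste(sort(arms), collapse = ", "))
  }
  styles <- arm_styles(arms, grayscale)
  draw <- do.call(rbind, lapply(arms, function(a)
    curve_draw_data(curves[[a]], a)))
  if (reversed_axis) {
    draw <- transform(draw, estimate = 1 - estimate,
                      ci_low = 1 - ci_high, ci_high = 1 - ci_low)
  }
  p <- ggplot(draw, aes(x = .data$time, group = .data$arm))
  if (bands)
    p <- p + geom_ribbon(aes(ymin = .data$ci_low, ymax = .data$ci_high,
                             fill = .data$arm),
                         stat = StatStepribbon, alpha = 0.15, colour = NA)
  p <- p +
    geom_step(aes(y = .data$estimate, colour = .data$arm,
                  linetype = .data$arm), linewidth = 0.6) +
    labs(x = "days since randomisation", y = ylab) +
    style_scales(styles, c("colour", "fill", "linetype")) + theme_harm()
  if (kind == "kaplan-meier plot")
    p <- p + coord_cartesian(ylim = c(0, 1))
  fig <- if (is.null(rtab)) p else {
    tp <- risk_table_panel(rtab, arms, styles) +
      scale_x_continuous(limits = range(draw$time))
    patchwork::wrap_plots(list(p, tp), ncol = 1, heights = c(3.2, 1))
  }
  list(figure = fig, styles = styles)
}

# step ribbon stat: hold each value until the next time point
StatStepribbon <- ggproto(
  "StatStepribbon", Stat,
  required_aes = c("x", "ymin", "ymax"),
  compute_group = function(data, scales, ...) {
    data <- data[order(data$x), ]
    n <- nrow(data)
    if (n < 2) return(data)
    v_idx <- rep(seq_len(n), each = 2)[-2 * n]   # hold value to next x
    x_idx <- rep(seq_len(n), each = 2)[-1]
    out <- data[v_idx, , drop = FALSE]
    out$x <- data$x[x_idx]
    out
  })

#' Kaplan-Meier plot with extended at-risk table
#'
#' Step curves of the event-free probability per arm with within-arm
#' confidence bands, and beneath them the extended table of participants
#' at risk, cumulatively censored and cumulatively evented at each grid
#' time, aligned to the time axis. Within-arm bands describe within-group
#' precision only; for a direct between-arm comparison see
#' [plot_survival_ratio()]. Competing risks are not modelled: where
#' competing events are material, cumulative-incidence methods should be
#' used for the underlying analysis instead.
#'
#' @param curves a named list of [km_estimate()] curves (one per arm), or a
#'   single curve.
#' @param rtab a [risk_table()] on the display grid (optional); its arms
#'   must match the curves.
#' @param bands draw confidence bands.
#' @param reversed_axis plot the cumulative proportion *with* the event
#'   (1 - S(t)), recommended for rare events.
#' @param grayscale distinct line styles instead of colour.
#' @return A `harm_figure`; `$table` holds the per-arm curves (row-bound,
#'   with an `arm` column) and the risk table exactly as supplied.
#' @export
plot_km <- function(curves, rtab = NULL, bands = TRUE,
                    reversed_axis = FALSE, grayscale = FALSE) {
  curves <- as_curve_list(curves)
  for (cv in curves)
    if (attr(cv, "kind") != "km")
      stop_validation("plot_km needs kind = \"km\" curves")
  built <- tte_figure("kaplan-meier plot", curves, rtab, bands, grayscale,
                      reversed_axis,
                      ylab = if (reversed_axis)
                        "cumulative proportion with event"
                      else "proportion event-free")
  curve_tab <- do.call(rbind, lapply(names(curves), function(a)
    cbind(arm = rep(a, nrow(curves[[a]])), as.data.frame(curves[[a]]))))
  new_harm_figure("kaplan-meier plot", built$figure,
                  table = list(curves = curve_tab, risk_table = rtab),
                  options = list(grayscale = grayscale, styles = built$styles,
                                 reversed_axis = reversed_axis,
                                 bands = bands))
}

#' Mean cumulative function plot
#'
#' Non-decreasing step curves of the mean cumulative number of events per
#' participant by arm, with within-arm confidence bands (suppressible:
#' overlaid bands for several arms can make the plot unreadable) and a
#' risk table of participants still under observation.
#'
#' @param curves named list of [mcf_estimate()] curves.
#' @param rtab optional [risk_table()].
#' @param bands draw confidence bands (`FALSE` recommended for > 2 arms).
#' @param grayscale distinct line styles instead of colour.
#' @return A `harm_figure`; `$table` holds the curves and risk table.
#' @export
plot_mcf <- function(curves, rtab = NULL, bands = TRUE, grayscale = FALSE) {
  curves <- as_curve_list(curves)
  for (cv in curves)
    if (attr(cv, "kind") != "mcf")
      stop_validation("plot_mcf needs kind = \"mcf\" curves")
  built <- tte_figure("mean cumulative function plot", curves, rtab, bands,
                      grayscale, reversed_axis = FALSE,
                      ylab = "mean cumulative events per participant")
  curve_tab <- do.call(rbind, lapply(names(curves), function(a)
    cbind(arm = rep(a, nrow(curves[[a]])), as.data.frame(curves[[a]]))))
  new_harm_figure("mean cumulative function plot", built$figure,
                  table = list(curves = curve_tab, risk_table = rtab),
                  options = list(grayscale = grayscale, styles = built$styles,
                                 bands = bands))
}

#' Survival ratio plot
#'
#' Step curve of the ratio (or difference) of event-free probabilities
#' between two arms with pointwise bootstrap bands, a reference line at
#' the value of no difference, and an indicator bar along the bottom that
#' changes appearance wherever the band excludes that value -- a signal
#' flag for potential adverse drug reactions, not a hypothesis test.
#'
#' @param ratio_curve a [survival_ratio()] result.
#' @param grayscale use black/hatched rather than green/red indicator
#'   segments.
#' @return A `harm_figure`; `$table` is the ratio curve; the indicator
#'   segments are exposed in `$options$indicator`.
#' @export
plot_survival_ratio <- function(ratio_curve, grayscale = FALSE) {
  stopifnot(inherits(ratio_curve, "survival_ratio_curve"))
  rc <- as.data.frame(ratio_curve)
  null <- attr(ratio_curve, "null")
  type <- attr(ratio_curve, "type")
  n <- nrow(rc)
  seg <- if (n > 1)
    data.frame(x = rc$time[-n], xend = rc$time[-1],
               flag = rc$excludes_unity[-n])
  else data.frame(x = rc$time, xend = rc$time, flag = rc$excludes_unity)
  cols <- if (grayscale) c(`FALSE` = "grey70", `TRUE` = "black")
          else c(`FALSE` = "#2E7D32", `TRUE` = "#C62828")
  fin <- rc[is.finite(rc$ci_high) & is.finite(rc$ci_low), ]
  y0 <- min(c(fin$ci_low, rc$estimate, null), na.rm = TRUE)
  y0 <- y0 - 0.05 * max(abs(c(fin$ci_high, rc$estimate, null)), na.rm = TRUE)
  # clamp unbounded band values for drawing only; the table keeps them exact
  draw <- rc
  cap <- max(c(fin$ci_high, rc$estimate, null), na.rm = TRUE)
  draw$ci_high[!is.finite(draw$ci_high)] <- cap
  draw$ci_low[!is.finite(draw$ci_low)] <- y0
  p <- ggplot(draw, aes(x = .data$time)) +
    geom_ribbon(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                stat = StatStepribbon, alpha = 0.15, fill = "grey30") +
    geom_hline(yintercept = null, linetype = "dashed", colour = "grey40") +
    geom_step(aes(y = .data$estimate), linewidth = 0.6) +
    geom_segment(data = seg,
                 aes(x = .data$x, xend = .data$xend, y = y0, yend = y0,
                     colour = .data$flag,
                     linetype = .data$flag),
                 linewidth = 2.2, show.legend = FALSE) +
    scale_colour_manual(values = cols,
                        breaks = c(FALSE, TRUE),
                        labels = c("band includes null", "band excludes null")) +
    scale_linetype_manual(values = c(`FALSE` = "solid",
                                     `TRUE` = if (grayscale) "11" else "solid")) +
    labs(x = "days since randomisation",
         y = if (type == "ratio") "survival ratio (reference / comparator)"
             else "difference in survival probability") +
    theme_harm()
  new_harm_figure("survival ratio plot", p, table = ratio_curve,
                  options = list(grayscale = grayscale, indicator = seg,
                                 null = null, type = type))
}
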