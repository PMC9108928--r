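# Endorsed displays for binary and count outcomes: the three-panel dot
# plot, the stacked bar chart of maximum severity, and the bar chart of
# event counts per participant.

#' Dot plot of absolute and comparative risks for multiple events
#'
#' Three aligned panels: absolute percentages per arm (left), the
#' comparative estimate with confidence intervals on a log axis and a
#' reference line at the value of no difference (centre), and the data
#' table of participants with events / events per arm (right, or centre if
#' preferred). Rows are ordered with the highest point estimate at the
#' top. Events with no events in either arm cannot be estimated; they are
#' footnoted.
#'
#' @param summary an [summarize_events()] table.
#' @param estimates an [effect_table()], ordered via [dot_plot_order()]
#'   (re-applied defensively). At most 3 active arms; more cannot be
#'   distinguished legibly.
#' @param grayscale render without colour (distinct shapes per arm).
#' @param table_panel `"right"` (default) or `"central"` placement of the
#'   data table.
#' @param abs_limits x-axis limits for the absolute panel; the default
#'   `c(0, max pct * 1.1)` avoids stretching rare events over a 0-100
#'   scale.
#' @return A `harm_figure`; `$table` holds `summary` and `estimates`
#'   exactly as supplied.
#' @export
plot_dot <- function(summary, estimates, grayscale = FALSE,
                     table_panel = c("right", "central"),
                     abs_limits = NULL) {
  stopifnot(inherits(summary, "event_summary"))
  table_panel <- match.arg(table_panel)
  estimates <- dot_plot_order(estimates)
  dropped <- attr(estimates, "dropped") %||% character()
  if (!setequal(c(estimates$label, dropped), summary$label))
    stop_validation("estimates and summary cover different event lists")
  if (length(unique(estimates$comparison)) > 3)
    stop_validation("more than 3 active arms cannot be distinguished on a dot plot")

  measure <- estimates$measure[1]
  null <- if (measure == "rd") 0 else 1
  ylev <- rev(unique(estimates$label))
  styles <- arm_styles(sort(unique(summary$arm)), grayscale)

  sm <- summary[summary$label %in% ylev, , drop = FALSE]
  sm$label <- factor(sm$label, levels = ylev)
  if (is.null(abs_limits)) abs_limits <- c(0, max(sm$pct) * 1.1)
  p_abs <- ggplot(sm, aes(x = .data$pct, y = .data$label,
                          colour = .data$arm, shape = .data$arm)) +
    geom_point(size = 2.4) +
    scale_x_continuous(limits = abs_limits) +
    labs(x = "% of participants with ≥1 event", y = NULL) +
    style_scales(styles, c("colour", "shape")) + theme_harm()

  est <- estimates
  est$label <- factor(est$label, levels = ylev)
  est$y <- as.numeric(est$label)
  dodge <- if (length(unique(est$comparison)) > 1)
    position_dodge(width = 0.5) else "identity"
  measure_lab <- c(rr = "relative risk", or = "odds ratio",
                   rd = "risk difference", irr = "rate ratio")[measure]
  p_est <- ggplot(est, aes(x = .data$point, y = .data$label,
                           group = .data$comparison)) +
    geom_vline(xintercept = null, linetype = "dashed", colour = "grey40") +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2, position = dodge) +
    geom_point(position = dodge, size = 1.8) +
    labs(x = paste0(measure_lab, " (", sprintf("%.0f", 100 * (1 - (attr(estimates, "alpha") %||% 0.05))), "% CI)"),
         y = NULL) +
    theme_harm() +
    theme(axis.text.y = element_blank())
  if (measure != "rd") p_est <- p_est + scale_x_log10()

  tab <- sm
  tab$cell <- sprintf("%d/%d (%d)", tab$n_participants, tab$arm_n,
                      tab$n_events)
  p_tab <- ggplot(tab, aes(x = .data$arm, y = .data$label,
                           label = .data$cell)) +
    geom_text(size = 2.8) +
    scale_x_discrete(position = "top") +
    labs(x = "n/N (events)", y = NULL) +
    theme_void() +
    theme(axis.text.x.top = element_text(size = 8),
          axis.title.x.top = element_text(size = 8))

  caption <- if (length(dropped))
    paste0("Not estimable (no events in either arm): ",
           paste(dropped, collapse = ", ")) else NULL
  fig <- if (table_panel == "right")
    patchwork::wrap_plots(list(p_abs, p_est, p_tab), nrow = 1,
                          widths = c(1.3, 1.3, 1))
  else
    patchwork::wrap_plots(list(p_abs, p_tab, p_est), nrow = 1,
                          widths = c(1.3, 1, 1.3))
  if (!is.null(caption))
    fig <- fig + patchwork::plot_annotation(caption = caption)

  new_harm_figure("dot plot", fig,
                  table = list(summary = summary, estimates = estimates),
                  options = list(grayscale = grayscale, styles = styles,
                                 table_panel = table_panel,
                                 abs_limits = abs_limits, null = null,
                                 dropped = dropped))
}

#' Stacked bar chart of maximum severity
#'
#' Horizontal bars of the percentage of participants with at least one
#' event, split by maximum severity grade, arms directly adjacent for each
#' event. The most severe grade is drawn closest to the vertical axis so
#' the most harmful categories can be compared across arms; bars are
#' labelled with participant counts. The severity gradient runs dark
#' (most severe) to light and works in grayscale.
#'
#' @param severity_table a [max_severity()] table.
#' @param grayscale greyscale gradient (the default gradient is already
#'   monochrome-safe; this switches arm-independent grey fills).
#' @param event_order optional label ordering, default descending total
#'   frequency.
#' @return A `harm_figure`; `$table` is the input table;
#'   `$options$layout` holds the computed segment coordinates
#'   (`label`, `arm`, `severity`, `xmin`, `xmax`).
#' @export
plot_stacked_severity <- function(severity_table, grayscale = FALSE,
                                  event_order = NULL) {
  st <- as.data.frame(severity_table)
  need <- c("arm", "label", "severity", "n", "arm_n")
  if (!all(need %in% names(st)))
    stop_validation("severity_table needs columns: %s",
                    paste(need, collapse = ", "))
  scale_levels <- levels(st$severity) %||% sort(unique(as.character(st$severity)))
  st$severity <- factor(as.character(st$severity), levels = scale_levels,
                        ordered = TRUE)
  st$pct <- 100 * st$n / st$arm_n

  if (is.null(event_order)) {
    tot <- tapply(st$n, st$label, sum)
    event_order <- names(sort(tot, decreasing = TRUE))
  }
  arms <- sort(unique(st$arm))

  # segment geometry: most severe first from the axis
  seg <- st[order(st$label, st$arm, -as.integer(st$severity)), ]
  key <- paste(seg$label, seg$arm)
  csum <- ave(seg$pct, key, FUN = cumsum)
  seg$xmax <- csum
  seg$xmin <- csum - seg$pct
  seg$row <- factor(paste(seg$label, seg$arm, sep = " — "),
                    levels = rev(as.vector(t(outer(event_order, arms,
                                                   paste, sep = " — ")))))
  totals <- aggregate(list(pct = seg$pct, n = seg$n),
                      by = list(row = seg$row), FUN = sum)

  sev_fill <- rev(grey.colors(length(scale_levels), start = 0.15, end = 0.85))
  names(sev_fill) <- scale_levels
  p <- ggplot(seg) +
    geom_rect(aes(xmin = .data$xmin, xmax = .data$xmax,
                  ymin = as.numeric(.data$row) - 0.38,
                  ymax = as.numeric(.data$row) + 0.38,
                  fill = .data$severity), colour = "white", linewidth = 0.2) +
    geom_text(data = totals, aes(x = .data$pct, y = as.numeric(.data$row),
                                 label = .data$n),
              hjust = -0.35, size = 2.8) +
    scale_y_continuous(breaks = seq_along(levels(seg$row)),
                       labels = levels(seg$row),
                       limits = c(0.5, nlevels(seg$row) + 0.5)) +
    scale_fill_manual(values = sev_fill, breaks = rev(scale_levels),
                      name = "maximum severity") +
    scale_x_continuous(expand = expansion(mult = c(0, 0.08))) +
    labs(x = "% of participants with ≥1 event (bar label: n participants)",
         y = NULL) +
    theme_harm()

  new_harm_figure("stacked bar chart", p, table = severity_table,
                  options = list(grayscale = grayscale,
                                 severity_fill = sev_fill,
                                 event_order = event_order,
                                 layout = seg[, c("label", "arm", "severity",
                                                  "pct", "n", "xmin", "xmax")]))
}

#' Bar chart of events per participant
#'
#' Percentage of participants by number of events experienced, per arm.
#' With two arms the bars are presented side by side in one panel; with
#' more than two arms, one panel per arm is stacked vertically with shared
#' axis limits.
#'
#' @param count_table an [event_counts()] table.
#' @param grayscale grey fills with distinct outlines.
#' @param labels annotate bars with participant counts.
#' @return A `harm_figure`; `$table` is the input table.
#' @export
plot_count_bars <- function(count_table, grayscale = FALSE, labels = FALSE) {
  ct <- as.data.frame(count_table)
  if (!all(c("arm", "k", "n", "pct") %in% names(ct)))
    stop_validation("count_table needs columns arm, k, n, pct")
  arms <- sort(unique(ct$arm))
  styles <- arm_styles(arms, grayscale)
  kk <- seq(0, max(ct$k))
  full <- merge(expand.grid(arm = arms, k = kk, stringsAsFactors = FALSE),
                ct, all.x = TRUE)
  full$n[is.na(full$n)] <- 0L
  full$pct[is.na(full$pct)] <- 0
  full$k <- factor(full$k, levels = kk)

  if (length(arms) <= 2) {
    p <- ggplot(full, aes(x = .data$k, y = .data$pct, fill = .data$arm)) +
      geom_col(position = position_dodge(width = 0.8), width = 0.7,
               colour = "grey20", linewidth = 0.2)
    if (labels)
      p <- p + geom_text(aes(label = .data$n),
                         position = position_dodge(width = 0.8),
                         vjust = -0.4, size = 2.6)
  } else {
    p <- ggplot(full, aes(x = .data$k, y = .data$pct, fill = .data$arm)) +
      geom_col(width = 0.7, colour = "grey20", linewidth = 0.2,
               show.legend = FALSE) +
      facet_grid(rows = vars(.data$arm))
    if (labels)
      p <- p + geom_text(aes(label = .data$n), vjust = -0.4, size = 2.6)
  }
  p <- p +
    labs(x = "number of events per participant", y = "% of participants") +
    style_scales(styles, "fill") + theme_harm()
  new_harm_figure("bar chart", p, table = count_table,
                  options = list(grayscale = grayscale, styles = styles,
                                 panels = if (length(arms) <= 2) 1L
                                 else length(arms)))
}
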