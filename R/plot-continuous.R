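# Continuous-outcome displays: line graph against normal limits, violin
# plot, kernel density plot, and the scatterplot matrix of baseline versus
# maximum values.

range_for <- function(ranges, outcome) {
  if (is.null(ranges) || !nrow(as.data.frame(ranges))) return(NULL)
  ranges <- as.data.frame(ranges)
  r <- ranges[ranges$outcome == outcome, , drop = FALSE]
  if (!nrow(r)) return(NULL)
  list(lower = r$lower[1], upper = r$upper[1])
}

ref_lines <- function(rng, vertical = FALSE) {
  if (is.null(rng)) return(NULL)
  vals <- c(rng$lower, rng$upper)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NULL)
  if (vertical) geom_vline(xintercept = vals, linetype = "dashed",
                           colour = "grey45")
  else geom_hline(yintercept = vals, linetype = "dashed", colour = "grey45")
}

#' Line graph of a continuous outcome over time
#'
#' Markers at the per-visit centre (mean or median), vertical bars for the
#' spread (SD of the raw values -- variability, not the standard error --
#' or the IQR; model-based summaries may be supplied as pre-computed rows
#' with `statistic = "model_ci"`), connecting lines per arm, horizontal
#' dashed reference lines at the limits of normal, and a participant-count
#' table beneath.
#'
#' @param summaries a [timepoint_summary()] table (any `statistic`).
#' @param rng normal range: list with `lower`/`upper`, or `NULL`. Missing
#'   range draws no reference lines and logs a warning.
#' @param grayscale distinct line styles/shapes instead of colour.
#' @return A `harm_figure`; `$table` is the summaries table.
#' @export
plot_line <- function(summaries, rng = NULL, grayscale = FALSE) {
  sm <- as.data.frame(summaries)
  need <- c("arm", "visit_time", "n", "center", "spread_low", "spread_high")
  if (!all(need %in% names(sm)))
    stop_validation("summaries needs columns: %s", paste(need, collapse = ", "))
  if (is.null(rng))
    warning("no normal range supplied: reference lines omitted",
            call. = FALSE)
  arms <- sort(unique(sm$arm))
  styles <- arm_styles(arms, grayscale)
  dodge <- position_dodge(width = diff(range(sm$visit_time)) / 60 + 1e-9)
  p <- ggplot(sm, aes(x = .data$visit_time, y = .data$center,
                      colour = .data$arm, shape = .data$arm,
                      linetype = .data$arm, group = .data$arm)) +
    ref_lines(rng) +
    geom_errorbar(aes(ymin = .data$spread_low, ymax = .data$spread_high),
                  width = 0, position = dodge, linetype = "solid") +
    geom_line(position = dodge, linewidth = 0.5) +
    geom_point(position = dodge, size = 2) +
    labs(x = "visit time (days)",
         y = sprintf("center ± spread (%s)", sm$statistic[1] %||% "")) +
    style_scales(styles, c("colour", "shape", "linetype")) + theme_harm()
  counts <- sm[order(sm$arm, sm$visit_time),
               c("arm", "visit_time", "n")]
  counts$rowlab <- factor(counts$arm, levels = rev(arms))
  tp <- ggplot(counts, aes(x = .data$visit_time, y = .data$rowlab,
                           label = .data$n)) +
    geom_text(size = 2.6) +
    scale_x_continuous(limits = range(sm$visit_time)) +
    labs(x = NULL, y = NULL) +
    theme_minimal(base_size = 9) +
    theme(panel.grid = element_blank(), axis.text.x = element_blank())
  fig <- patchwork::wrap_plots(list(p, tp), ncol = 1, heights = c(4, 1))
  new_harm_figure("line graph", fig, table = summaries,
                  options = list(grayscale = grayscale, styles = styles,
                                 range = rng))
}

#' Violin plot of a continuous outcome by visit and arm
#'
#' Mirrored kernel-density outlines per (arm, visit) cell, overlaid with a
#' hollow circle at the median, a narrow box for the interquartile range,
#' and whiskers to the minimum and maximum; dashed lines mark the limits
#' of normal. Cells with fewer than two distinct values are drawn as a
#' point and whisker only. The `half` option draws the density on one side
#' only, which avoids duplicating the mirrored information.
#'
#' @param dataset a `trial_dataset`.
#' @param outcome outcome name.
#' @param grayscale grey outlines.
#' @param half half-violin (density on one side only).
#' @return A `harm_figure`; `$table` is
#'   `timepoint_summary(dataset, outcome, "median_iqr")`; densities per
#'   cell sit in `$options$densities`.
#' @export
plot_violin <- function(dataset, outcome, grayscale = FALSE, half = FALSE) {
  stopifnot(inherits(dataset, "trial_dataset"))
  summaries <- timepoint_summary(dataset, outcome, "median_iqr")
  m <- dataset$measurements
  m <- m[m$outcome == outcome, , drop = FALSE]
  m$arm <- dataset$roster$arm[match(m$participant_id,
                                    dataset$roster$participant_id)]
  arms <- sort(unique(m$arm))
  styles <- arm_styles(arms, grayscale)
  visits <- sort(unique(m$visit_time))
  gap <- if (length(visits) > 1) min(diff(visits)) else 1
  width <- 0.38 * gap / length(arms)
  offs <- (seq_along(arms) - (length(arms) + 1) / 2) * gap / (length(arms) + 0.3)

  polys <- list(); dens <- list(); mins <- list()
  for (vi in seq_along(visits)) for (ai in seq_along(arms)) {
    v <- m$value[m$visit_time == visits[vi] & m$arm == arms[ai]]
    if (!length(v)) next
    cx <- visits[vi] + offs[ai]
    mins[[length(mins) + 1]] <- data.frame(
      arm = arms[ai], visit_time = visits[vi], x = cx,
      ymin = min(v), ymax = max(v))
    if (length(unique(v)) < 2) next
    k <- kde_estimate(v)
    dens[[length(dens) + 1]] <- data.frame(
      arm = arms[ai], visit_time = visits[vi], grid = k$grid,
      density = k$density, bandwidth = k$bandwidth)
    w <- k$density / max(k$density) * width
    poly <- if (half)
      data.frame(x = c(cx + w, rep(cx, length(w))),
                 y = c(k$grid, rev(k$grid)))
    else
      data.frame(x = c(cx + w, cx - rev(w)), y = c(k$grid, rev(k$grid)))
    poly$arm <- arms[ai]
    poly$cell <- paste(arms[ai], visits[vi])
    polys[[length(polys) + 1]] <- poly
  }
  polys <- if (length(polys)) do.call(rbind, polys) else NULL
  mins <- do.call(rbind, mins)
  sm <- summaries
  sm$x <- sm$visit_time + offs[match(sm$arm, arms)]
  box_w <- width * 0.18

  p <- ggplot() + ref_lines(range_for(dataset$ranges, outcome))
  if (!is.null(polys))
    p <- p + geom_polygon(data = polys,
                          aes(x = .data$x, y = .data$y, group = .data$cell,
                              colour = .data$arm, fill = .data$arm),
                          alpha = 0.25, linewidth = 0.4)
  p <- p +
    geom_linerange(data = mins, aes(x = .data$x, ymin = .data$ymin,
                                    ymax = .data$ymax), linewidth = 0.3) +
    geom_rect(data = sm, aes(xmin = .data$x - box_w, xmax = .data$x + box_w,
                             ymin = .data$spread_low,
                             ymax = .data$spread_high),
              fill = "grey25") +
    geom_point(data = sm, aes(x = .data$x, y = .data$center), shape = 1,
               size = 2, stroke = 0.9, colour = "black", fill = "white") +
    labs(x = "visit time (days)", y = outcome) +
    style_scales(styles, c("colour", "fill")) + theme_harm()
  new_harm_figure("violin plot", p, table = summaries,
                  options = list(grayscale = grayscale, styles = styles,
                                 half = half,
                                 densities = if (length(dens))
                                   do.call(rbind, dens) else NULL))
}

#' Kernel density plot by arm
#'
#' Overlaid per-arm Gaussian kernel densities of a continuous outcome or a
#' change score, with vertical dashed reference lines at the limits of
#' normal. Distributions are compared informally; repeated-measures
#' information is not displayed.
#'
#' @param values_by_arm a named list of numeric vectors, or a data frame
#'   with an `arm` column and a `value` (or `score`) column, e.g.
#'   [change_scores()] output.
#' @param rng normal range list (`lower`/`upper`) or `NULL`.
#' @param grayscale distinct line styles.
#' @return A `harm_figure`; `$table` is a data frame `arm`, `grid`,
#'   `density`, `bandwidth` holding the exact [kde_estimate()] output per
#'   arm.
#' @export
plot_kde <- function(values_by_arm, rng = NULL, grayscale = FALSE) {
  if (is.data.frame(values_by_arm)) {
    vcol <- intersect(c("score", "value"), names(values_by_arm))[1]
    if (is.na(vcol) || !"arm" %in% names(values_by_arm))
      stop_validation("data frame input needs `arm` and `value`/`score` columns")
    values_by_arm <- split(values_by_arm[[vcol]], values_by_arm$arm)
  }
  arms <- names(values_by_arm)
  styles <- arm_styles(arms, grayscale)
  tab <- do.call(rbind, lapply(arms, function(a) {
    k <- kde_estimate(values_by_arm[[a]])
    data.frame(arm = a, grid = k$grid, density = k$density,
               bandwidth = k$bandwidth, stringsAsFactors = FALSE)
  }))
  p <- ggplot(tab, aes(x = .data$grid, y = .data$density,
                       colour = .data$arm, linetype = .data$arm)) +
    ref_lines(rng, vertical = TRUE) +
    geom_line(linewidth = 0.6) +
    labs(x = "value", y = "density") +
    style_scales(styles, c("colour", "linetype")) + theme_harm()
  new_harm_figure("kernel density plot", p, table = tab,
                  options = list(grayscale = grayscale, styles = styles,
                                 range = rng))
}

#' Scatterplot matrix of baseline versus maximum values
#'
#' One panel per outcome: each participant's baseline value on the
#' horizontal axis against their maximum post-baseline value on the
#' vertical axis, per-arm symbols with transparency (solid symbols
#' occlude), dashed normal-limit lines forming quadrants, an optional
#' identity diagonal, and participant-id labels on points falling outside
#' the normal limits (e.g. normal at baseline, abnormal on treatment: the
#' quadrant of most concern when higher is worse).
#'
#' @param tables named list of [baseline_max()] tables, one per outcome
#'   (names are outcome labels).
#' @param ranges `ranges` data frame (`outcome`, `lower`, `upper`) or
#'   `NULL`.
#' @param grayscale distinct shapes instead of colour.
#' @param identity draw the x = y diagonal.
#' @param label_outliers label points outside the normal limits.
#' @return A `harm_figure`; `$table` is the supplied list of tables.
#' @export
plot_scatter_matrix <- function(tables, ranges = NULL, grayscale = FALSE,
                                identity = TRUE, label_outliers = TRUE) {
  if (is.data.frame(tables)) tables <- list(outcome = tables)
  if (is.null(names(tables)))
    stop_validation("tables must be a named list (names are outcome labels)")
  all <- do.call(rbind, lapply(names(tables), function(o)
    cbind(outcome = o, as.data.frame(tables[[o]]))))
  arms <- sort(unique(all$arm))
  styles <- arm_styles(arms, grayscale)

  refs <- NULL
  all$outlier <- FALSE
  if (!is.null(ranges)) {
    rg <- as.data.frame(ranges)
    refs <- rg[rg$outcome %in% names(tables), , drop = FALSE]
    lo <- refs$lower[match(all$outcome, refs$outcome)]
    hi <- refs$upper[match(all$outcome, refs$outcome)]
    out_of <- function(v) (!is.na(lo) & v < lo) | (!is.na(hi) & v > hi)
    all$outlier <- out_of(all$baseline) | out_of(all$maximum)
  }
  p <- ggplot(all, aes(x = .data$baseline, y = .data$maximum)) +
    facet_wrap(vars(.data$outcome), scales = "free")
  if (identity)
    p <- p + geom_abline(slope = 1, intercept = 0, colour = "grey75",
                         linewidth = 0.3)
  if (!is.null(refs) && nrow(refs)) {
    rl <- rbind(data.frame(outcome = refs$outcome, v = refs$lower),
                data.frame(outcome = refs$outcome, v = refs$upper))
    rl <- rl[!is.na(rl$v), , drop = FALSE]
    p <- p +
      geom_vline(data = rl, aes(xintercept = .data$v), linetype = "dashed",
                 colour = "grey45") +
      geom_hline(data = rl, aes(yintercept = .data$v), linetype = "dashed",
                 colour = "grey45")
  }
  p <- p + geom_point(aes(colour = .data$arm, shape = .data$arm),
                      alpha = 0.6, size = 1.8)
  if (label_outliers && any(all$outlier))
    p <- p + geom_text(data = all[all$outlier, , drop = FALSE],
                       aes(label = .data$participant_id), size = 2.4,
                       vjust = -0.8, check_overlap = TRUE)
  p <- p + labs(x = "baseline value", y = "maximum post-baseline value") +
    style_scales(styles, c("colour", "shape")) + theme_harm()
  new_harm_figure("scatterplot matrix", p, table = tables,
                  options = list(grayscale = grayscale, styles = styles,
                                 labelled = all$participant_id[all$outlier],
                                 panels = length(tables)))
}
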