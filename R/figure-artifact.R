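# Figure artifacts: every plot builder returns the rendered figure
# together with the exact summary table it displays, plus the resolved
# options (including the per-arm style map used for grayscale rendering).

new_harm_figure <- function(kind, figure, table, options) {
  stopifnot(kind %in% endorsed_plots())
  structure(list(kind = kind, figure = figure, table = table,
                 options = options), class = "harm_figure")
}

#' @export
print.harm_figure <- function(x, ...) {
  cat(sprintf("<harm_figure: %s>\n", x$kind))
  print(x$figure)
  invisible(x)
}

#' @export
plot.harm_figure <- function(x, ...) print(x$figure)

# per-arm style map: colour-blind-safe palette by default, or grey shades
# with distinct line types / point shapes when grayscale output is needed
arm_styles <- function(arms, grayscale = FALSE) {
  k <- length(arms)
  if (grayscale) {
    data.frame(arm = arms,
               colour = grey.colors(k, start = 0, end = 0.55),
               linetype = c("solid", "22", "42", "12", "44", "13")[
                 (seq_len(k) - 1) %% 6 + 1],
               shape = c(16, 17, 15, 3, 7, 8)[(seq_len(k) - 1) %% 6 + 1],
               stringsAsFactors = FALSE)
  } else {
    pal <- c("#0072B2", "#D55E00", "#009E73", "#CC79A7", "#E69F00",
             "#56B4E9")
    data.frame(arm = arms, colour = pal[(seq_len(k) - 1) %% 6 + 1],
               linetype = "solid",
               shape = c(16, 17, 15, 3, 7, 8)[(seq_len(k) - 1) %% 6 + 1],
               stringsAsFactors = FALSE)
  }
}

style_scales <- function(styles, which = c("colour", "fill", "linetype",
                                           "shape")) {
  scales <- list(
    colour = function() scale_colour_manual(
      values = setNames(styles$colour, styles$arm)),
    fill = function() scale_fill_manual(
      values = setNames(styles$colour, styles$arm)),
    linetype = function() scale_linetype_manual(
      values = setNames(styles$linetype, styles$arm)),
    shape = function() scale_shape_manual(
      values = setNames(styles$shape, styles$arm)))
  lapply(which, function(w) scales[[w]]())
}

theme_harm <- function() {
  theme_minimal(base_size = 10) +
    theme(panel.grid.minor = element_blank(),
          legend.position = "bottom",
          plot.title = element_text(size = 11))
}

# expand a step function into ribbon-friendly coordinates: value holds from
# each time until the next
step_ribbon <- function(df, timecol = "time", from0 = TRUE, init = NULL) {
  if (!nrow(df)) return(df)
  if (from0 && !is.null(init)) {
    first <- df[1, , drop = FALSE]
    first[[timecol]] <- 0
    for (nm in names(init)) first[[nm]] <- init[[nm]]
    df <- rbind(first, df)
  }
  df
}

#' Save a figure artifact and its companion table
#'
#' Writes the figure in one or more formats (vector formats first-class)
#' and the underlying summary table(s) as CSV alongside it.
#'
#' @param artifact a `harm_figure`.
#' @param path output path without extension.
#' @param formats subset of `"svg"`, `"pdf"`, `"png"`.
#' @param width,height device size in inches.
#' @param table also write the companion CSV table(s).
#' @return Invisibly, the files written.
#' @export
save_figure <- function(artifact, path, formats = c("svg", "csv"),
                        width = 8, height = 6, table = TRUE) {
  stopifnot(inherits(artifact, "harm_figure"))
  written <- character()
  if ("svg" %in% formats && !capabilities("cairo"))
    formats[formats == "svg"] <- "pdf"   # vector fallback
  for (fmt in setdiff(formats, "csv")) {
    f <- paste0(path, ".", fmt)
    ggsave(f, plot = artifact$figure, width = width, height = height,
           device = fmt)
    written <- c(written, f)
  }
  if (table) {
    tabs <- artifact$table
    if (is.data.frame(tabs)) tabs <- list(table = tabs)
    for (nm in names(tabs)) {
      if (!is.data.frame(tabs[[nm]])) next
      f <- paste0(path, "_", nm, ".csv")
      write.csv(tabs[[nm]], f, row.names = FALSE)
      written <- c(written, f)
    }
  }
  invisible(written)
}
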