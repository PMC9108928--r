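Package: harmvis
Title: Visualising Harm Outcomes in Randomised Controlled Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds the ten consensus-endorsed visualisations for harm
    (adverse event) outcomes in parallel-arm randomised controlled trials:
    the three-panel dot plot of absolute and relative risks, stacked bar
    charts of maximum severity, bar charts of event counts, Kaplan-Meier
    plots with extended at-risk tables, mean cumulative function plots for
    recurrent events, survival ratio plots with bootstrap confidence bands,
    line graphs against normal ranges, violin plots, kernel density plots,
    and scatterplot matrices of baseline versus maximum laboratory values.
    Each figure returns the exact summary table it displays. Also provides
    the comparative estimators the plots embed (relative risk, odds ratio,
    risk difference and incidence rate ratio with Wald intervals and the
    half-event zero-cell correction), a decision tree that recommends a
    plot from outcome characteristics, a synthetic two-arm trial generator
    for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    patchwork,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
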