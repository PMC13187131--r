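#' Published continental extent summary
#'
#' The bundled summary table of estimated US tidal wetland extent by coast
#' and class for 1985 and 2023 (km^2, with 95% CI half-widths), together
#' with the reported change trends (km^2 per year) and trend strengths
#' (km^2 per year^2) where significant. Used by the reporting stage to
#' recompute cumulative change and percentage-loss figures from the printed
#' extents.
#'
#' @return Data frame with columns `region`, `class`, `extent_1985`,
#'   `extent_1985_ci`, `extent_2023`, `extent_2023_ci`, `trend`, `trend_lo`,
#'   `trend_hi`, `strength`, `strength_lo`, `strength_hi` (trend/strength
#'   `NA` where not significant or not applicable).
#' @export
extent_summary_table <- function() {
  path <- system.file("extdata", "conus_extent_summary.csv",
                      package = "tidewetland", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Net change arithmetic from an extent summary
#'
#' Recomputes, from first/last-year extents, the net change and its
#' percentage of the initial extent for each region x class row.
#'
#' @param tab An extent table as returned by [extent_summary_table()].
#' @return `tab` with `net_change` (km^2) and `pct_change` (% of the
#'   first-year extent, negative = loss) appended.
#' @export
extent_net_change <- function(tab = extent_summary_table()) {
  tab$net_change <- tab$extent_2023 - tab$extent_1985
  tab$pct_change <- 100 * tab$net_change / tab$extent_1985
  tab
}
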