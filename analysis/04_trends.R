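#!/usr/bin/env Rscript
# Stage 4 -- temporal trend analyses.
# Sen's slope + Mann-Kendall on the mapped annual wetland area, the
# two-level moving-window trend strength (acceleration/deceleration), the
# marsh area profile across 0.1 m elevation bins, and the change arithmetic
# of the bundled continental extent summary.

suppressPackageStartupMessages(library(tidewetland))

res <- if (file.exists("scratch/pipeline_run.rds")) {
  readRDS("scratch/pipeline_run.rds")
} else {
  run_pipeline(read_run_config(demo_config_path()))
}
dir.create("results", showWarnings = FALSE)

tt <- res$trend_total
message(sprintf(
  "wetland area trend: %+.5f km2/yr [%.5f, %.5f], MK p = %.3g -> %s",
  tt$slope, tt$slope_ci[1], tt$slope_ci[2], tt$p, tt$symbol))
message(sprintf("trend strength: %+.6f km2/yr2 (MK p = %.3g)",
                tt$strength, tt$strength_p))

total_row <- data.frame(zone = "total", class = "wetland",
                        slope = tt$slope, slope_lo = tt$slope_ci[1],
                        slope_hi = tt$slope_ci[2], p = tt$p,
                        strength = tt$strength, strength_p = tt$strength_p,
                        symbol = tt$symbol)
elev_rows <- do.call(rbind, lapply(names(res$trend_elev), function(z) {
  tr <- res$trend_elev[[z]]
  if (is.null(tr)) return(NULL)
  data.frame(zone = paste0("elev_bin_", z), class = "tidal_marsh",
             slope = tr$slope, slope_lo = tr$slope_ci[1],
             slope_hi = tr$slope_ci[2], p = tr$p, strength = tr$strength,
             strength_p = tr$strength_p, symbol = tr$symbol)
}))
write.csv(rbind(total_row, elev_rows), "results/trends.csv", row.names = FALSE)
message(sprintf("elevation bins with marsh: %d of %d (0.1 m bins, -1 to 2 m)",
                sum(!vapply(res$trend_elev, is.null, logical(1))),
                n_bins(-1, 2, 0.1)))

tab <- extent_net_change()
write.csv(tab, "results/extent_change_summary.csv", row.names = FALSE)
conus <- tab[tab$region == "conus" & tab$class == "total", ]
message(sprintf(
  "continental summary: net %+d km2 (%.2f%% of 1985), trend %.2f km2/yr, strength %.2f km2/yr2",
  conus$net_change, conus$pct_change, conus$trend, conus$strength))
message("wrote results/trends.csv, results/extent_change_summary.csv")
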