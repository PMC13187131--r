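#!/usr/bin/env Rscript
# Stage 3 -- change typology.
# Classifies every pixel's 39-year label trajectory into the change strata
# (stable / permanent loss / permanent gain / fluctuation / other change)
# and extracts mangrove dieback events (runs of the dieback condition class
# persisting more than one growing season).

suppressPackageStartupMessages(library(tidewetland))

res <- if (file.exists("scratch/pipeline_run.rds")) {
  readRDS("scratch/pipeline_run.rds")
} else {
  run_pipeline(read_run_config(demo_config_path()))
}
dir.create("results", showWarnings = FALSE)

tab <- as.data.frame(table(mapped = res$strata, truth = res$truth_strata))
write.csv(tab, "results/strata_confusion.csv", row.names = FALSE)

strata_area <- as.data.frame(table(stratum = res$strata))
strata_area$area_km2 <- strata_area$Freq * res$scene$pixel_area / 1e6
write.csv(strata_area[, c("stratum", "area_km2")],
          "results/strata_areas.csv", row.names = FALSE)

die <- do.call(rbind, lapply(seq_len(ncol(res$maps)), function(p) {
  ev <- dieback_events(res$maps[, p], res$scene$years)
  if (nrow(ev)) cbind(pixel = p, ev) else NULL
}))
if (!is.null(die)) write.csv(die, "results/dieback_events.csv", row.names = FALSE)

message(sprintf("strata: %s",
                paste(sprintf("%s %d", strata_area$stratum, strata_area$Freq),
                      collapse = ", ")))
agree <- mean(res$strata == res$truth_strata)
message(sprintf("stratum agreement with truth: %.1f%% of pixels", 100 * agree))
if (!is.null(die)) {
  message(sprintf("dieback events: %d (%d recovered), median duration %d yr",
                  nrow(die), sum(die$recovered), as.integer(median(die$duration))))
}
message("wrote results/strata_confusion.csv, results/strata_areas.csv, results/dieback_events.csv")
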