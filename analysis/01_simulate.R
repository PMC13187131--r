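#!/usr/bin/env Rscript
# Stage 1 -- simulate the study system.
# Generates the demonstration scene (40 x 40 pixels, 1985-2023, 32-day
# cadence): a tidally confounded coastal gradient with hurricane losses,
# gradual drowning, mangrove encroachment, a restoration gain, mangrove
# dieback and a direct conversion. Writes the truth bookkeeping that later
# stages are judged against.

suppressPackageStartupMessages(library(tidewetland))

cfg <- read_run_config(demo_config_path())
scene <- generate_scene(cfg$scene, seed = cfg$seed)
dir.create("results", showWarnings = FALSE)

tw <- truth_area_series(scene)
write.csv(tw, "results/truth_wetland_area.csv", row.names = FALSE)
write_ascii_grid(scene$dem, "results/dem.asc")
jsonlite::write_json(
  lapply(scene$events, function(e) e[c("kind", "driver", "onset", "target",
                                       "recovery", "duration", "recoverable")]),
  "results/truth_events.json", auto_unbox = TRUE, digits = NA, null = "null")

net <- tw$area_km2[nrow(tw)] - tw$area_km2[1]
message(sprintf("scene: %d pixels, %d observations/pixel, %d events",
                scene$nrow * scene$ncol, length(scene$times),
                length(scene$events)))
message(sprintf("truth wetland extent: %.4f km2 (1985) -> %.4f km2 (2023), net %+.4f km2",
                tw$area_km2[1], tw$area_km2[nrow(tw)], net))
message("wrote results/truth_wetland_area.csv, results/dem.asc, results/truth_events.json")
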