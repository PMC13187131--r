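#!/usr/bin/env Rscript
# Stage 5 -- design-based estimation.
# Post-stratified accuracy and error-adjusted areas for the annual cover
# maps, change-stratum accuracy under the 20/20/20/60 five-year design, and
# stratified driver attribution with 1000-iteration bootstrap intervals.

suppressPackageStartupMessages(library(tidewetland))

res <- if (file.exists("scratch/pipeline_run.rds")) {
  readRDS("scratch/pipeline_run.rds")
} else {
  run_pipeline(read_run_config(demo_config_path()))
}
dir.create("results", showWarnings = FALSE)

acc <- res$accuracy
cls <- names(wetland_classes())[match(acc$classes, wetland_classes())]
acc_tab <- data.frame(class = cls,
                      users_accuracy = unname(acc$users_accuracy),
                      producers_accuracy = unname(acc$producers_accuracy),
                      area_km2 = unname(acc$areas),
                      area_ci_km2 = unname(acc$areas_ci))
write.csv(acc_tab, "results/accuracy.csv", row.names = FALSE)
message(sprintf("cover maps: overall accuracy %.2f%% (n = %d reference pixel-years)",
                100 * acc$overall_accuracy, sum(acc$counts)))
for (i in seq_len(nrow(acc_tab))) {
  message(sprintf("  %-18s UA %.3f  PA %.3f  error-adjusted area %.4f +/- %.4f km2",
                  acc_tab$class[i], acc_tab$users_accuracy[i],
                  acc_tab$producers_accuracy[i], acc_tab$area_km2[i],
                  acc_tab$area_ci_km2[i]))
}

if (is.null(res$change_accuracy$error)) {
  ca <- res$change_accuracy
  message(sprintf("change strata: overall accuracy %.2f%%",
                  100 * ca$overall_accuracy))
}

if (!is.null(res$drivers)) {
  write.csv(res$drivers$cumulative, "results/driver_proportions.csv",
            row.names = FALSE)
  write.csv(res$drivers$per_phase, "results/driver_per_phase.csv",
            row.names = FALSE)
  loss <- subset(res$drivers$cumulative, stratum == "permanent_loss")
  message("cumulative driver shares of permanent loss (95% bootstrap CI):")
  for (i in seq_len(nrow(loss))) {
    message(sprintf("  %-17s %.2f [%.2f, %.2f]", loss$driver[i],
                    loss$proportion[i], loss$lo[i], loss$hi[i]))
  }
  if (!is.null(res$driver_trends)) {
    write.csv(res$driver_trends, "results/driver_trends.csv", row.names = FALSE)
  }
}
message("wrote results/accuracy.csv, results/driver_proportions.csv, results/driver_trends.csv")
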