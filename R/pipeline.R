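#' Run the full monitoring pipeline on a simulated scene
#'
#' Executes simulate, prep, detect, classify, post-process, typology,
#' trends and estimation, and (optionally) writes maps, tables and a run
#' manifest. Re-running with the same configuration and seed reproduces all
#' outputs exactly.
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param seed Overrides the config seed when given.
#' @param verbose Print stage progress.
#' @return List with `scene`, `classifier`, `pixel_results`, `maps_raw`,
#'   `maps` (post-processed `n_years x n_pixels`), `strata` (per-pixel
#'   trajectory class), `areas` (annual class areas), `trend_total`
#'   (wetland-extent trend), `trend_elev` (per elevation bin),
#'   `accuracy` (post-stratified cover estimates), `change_accuracy`,
#'   `drivers`, `driver_trends`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL, verbose = FALSE) {
  seed <- as.integer(seed %||% config$seed)
  say <- function(...) if (verbose) message(sprintf(...))
  codes <- wetland_classes()
  t_start <- Sys.time()

  say("simulate: generating scene")
  scene <- generate_scene(config$scene, seed = seed)
  years <- scene$years
  npx <- scene$nrow * scene$ncol

  say("prep: compositing and tide attachment")
  prepped <- prep_scene(scene, seed = seed + 1L)

  say("classify: training segment classifier")
  cls_cfg <- config$classifier
  train <- training_segments(n_per_class = cls_cfg$n_per_class %||% 40,
                             spectra = config$scene$spectra,
                             tide = config$scene$tide,
                             noise_scale = config$scene$noise_scale,
                             d_full = config$scene$d_full,
                             seed = seed + 2L)
  classifier <- train_segment_classifier(train$features, train$labels,
                                         seed = seed + 3L,
                                         ntree = cls_cfg$ntree %||% 300)

  say("detect: break detection over %d pixels", npx)
  bp <- config$breaks
  pixel_results <- vector("list", npx)
  for (p in seq_len(npx)) {
    segs <- detect_breaks(prepped[[p]], bp)
    labs <- lapply(segs, function(sg) {
      if (is.null(sg$fits)) return(NULL)
      recognize_segment_cover(prepped[[p]], sg, classifier, bp)
    })
    pixel_results[[p]] <- list(segments = segs, labels = labs)
  }
  n_breaks <- sum(vapply(pixel_results, function(pr)
    sum(vapply(pr$segments, function(s) s$ended_by_break, logical(1))), numeric(1)))

  say("maps: rasterizing %d annual maps", length(years))
  maps_raw <- annual_maps(pixel_results, years)

  say("clean: object-based post-processing")
  pp <- config$postprocess
  mmu <- pp$min_pixels %||% 4
  wtab <- if (!is.null(pp$water_table)) as.data.frame(pp$water_table)
          else water_distance_table()
  maps <- maps_raw
  for (yi in seq_along(years)) {
    g <- matrix(maps_raw[yi, ], scene$nrow, scene$ncol, byrow = TRUE)
    g <- postprocess_map(g, min_pixels = mmu, table = wtab)
    maps[yi, ] <- as.integer(t(g))
  }

  say("typology: trajectory strata")
  strata <- trajectory_strata(maps)
  truth_strata <- trajectory_strata(scene$truth)

  say("trends: area series and Sen/MK analyses")
  areas <- aggregate_areas(maps, years)
  wet_area <- stats::aggregate(area_km2 ~ year,
    data = areas[areas$class %in% names(codes)[codes %in% wetland_extent_classes()], ],
    FUN = sum)
  trend_total <- trend_analysis(wet_area$area_km2,
                                window = config$trend$window %||% 10,
                                alpha = config$trend$alpha %||% 0.05)
  dem_px <- as.numeric(t(scene$dem))
  areas_elev <- aggregate_areas(maps, years,
                                zones = list(values = dem_px, from = -1, to = 2, by = 0.1))
  marsh_elev <- areas_elev[areas_elev$class == "tidal_marsh", ]
  trend_elev <- lapply(split(marsh_elev, marsh_elev$zone), function(sub) {
    sub <- sub[order(sub$year), ]
    if (sum(sub$area_km2) == 0) return(NULL)
    trend_analysis(sub$area_km2, window = config$trend$window %||% 10)
  })

  est_cfg <- config$estimation
  est_seed <- as.integer(est_cfg$seed %||% (seed + 4L))
  say("estimate: post-stratified accuracy")
  accuracy <- assess_cover_accuracy(maps, scene$truth,
                                    total_n = est_cfg$total_n %||% 1200,
                                    min_per_class = est_cfg$min_per_class %||% 150,
                                    seed = est_seed)

  say("estimate: change accuracy and drivers")
  ca <- assess_change_and_drivers(maps, scene, strata, truth_strata,
                                  n_boot = est_cfg$n_boot %||% 1000,
                                  seed = est_seed + 1L)

  manifest <- list(
    package_version = as.character(utils::packageVersion("tidewetland")),
    seed = seed, estimation_seed = est_seed,
    grid = c(scene$nrow, scene$ncol), years = range(years),
    n_observations = length(scene$times), n_breaks = n_breaks,
    n_training_segments = length(train$labels),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))

  out <- list(scene = scene, classifier = classifier,
              pixel_results = pixel_results, maps_raw = maps_raw, maps = maps,
              strata = strata, truth_strata = truth_strata,
              areas = areas, wet_area = wet_area,
              trend_total = trend_total, trend_elev = trend_elev,
              accuracy = accuracy, change_accuracy = ca$accuracy,
              drivers = ca$drivers, driver_trends = ca$trends,
              manifest = manifest)
  if (!is.null(out_dir)) write_run_outputs(out, out_dir)
  out
}

# stratified cover-accuracy assessment against the truth stack
assess_cover_accuracy <- function(maps, truth, total_n = 1200,
                                  min_per_class = 150, seed = 1L) {
  stopifnot(all(dim(maps) == dim(truth)))
  cells <- which(maps > 0)          # pixel-years with a mapped label
  lab <- maps[cells]
  present <- sort(unique(lab))
  prop <- as.numeric(table(factor(lab, levels = present))) / length(lab)
  alloc <- allocate_sample(stats::setNames(prop, present), total_n,
                           min_per_class = min_per_class)
  k <- length(present)
  counts <- matrix(0L, k, k, dimnames = list(map = present, ref = present))
  withr::with_seed(seed, {
    for (i in seq_len(k)) {
      pool <- cells[lab == present[i]]
      n_i <- min(alloc[i], length(pool))
      pick <- if (length(pool) == 1) pool else sample(pool, n_i)
      ref <- truth[pick]
      ref[!ref %in% present] <- present[which.max(prop)]  # guard: unmapped truth class
      counts[i, ] <- as.integer(table(factor(ref, levels = present)))
    }
  })
  est <- post_stratified_estimates(counts, weights = prop,
                                   total_area = length(cells) * PIXEL_AREA_M2 / 1e6)
  est$counts <- counts
  est$classes <- present
  est
}

# change-stratum accuracy (20/20/20/60 per phase) + driver attribution
assess_change_and_drivers <- function(maps, scene, strata, truth_strata,
                                      n_boot = 1000, seed = 1L) {
  years <- scene$years
  phases <- data.frame(start = seq(1986, 2016, by = 5))
  phases$end <- phases$start + 4
  phases$label <- sprintf("%d-%d", phases$start, phases$end)
  change_types <- c("permanent_gain", "permanent_loss", "fluctuation")

  first_change_year <- vapply(seq_len(ncol(maps)), function(p) {
    tc <- classify_trajectory(maps[, p])
    if (is.na(tc$first_change)) NA_real_ else years[tc$first_change]
  }, numeric(1))
  phase_of <- function(yr) {
    i <- which(yr >= phases$start & yr <= phases$end)
    if (length(i)) phases$label[i] else NA_character_
  }
  px_phase <- vapply(first_change_year, phase_of, character(1))

  # mapped change area per phase x stratum (pixels of that stratum changing then)
  pa <- NULL
  for (ph in phases$label) for (st in c(change_types, "others")) {
    sel <- if (st == "others") is.na(px_phase) | !strata %in% change_types
           else !is.na(px_phase) & px_phase == ph & strata == st
    if (st == "others") sel <- sel   # others pool is phase-independent
    pa <- rbind(pa, data.frame(phase = ph, stratum = st,
                               area = sum(sel) * scene$pixel_area / 1e6))
  }
  design <- suppressWarnings(change_accuracy_design(pa, seed = seed))

  # draw samples, read reference stratum from truth, driver from the ledger
  samples <- NULL
  counts <- matrix(0L, 4, 4, dimnames = list(map = c(change_types, "others"),
                                             ref = c(change_types, "others")))
  withr::with_seed(seed, {
    for (r in seq_len(nrow(design))) {
      ph <- design$phase[r]; st <- design$stratum[r]
      pool <- if (st == "others") which(!strata %in% change_types)
              else which(!is.na(px_phase) & px_phase == ph & strata == st)
      if (!length(pool)) next
      pick <- pool[sample.int(length(pool), min(design$n[r], length(pool)),
                              replace = length(pool) < design$n[r])]
      ref <- truth_strata[pick]
      ref[!ref %in% change_types] <- "others"
      counts[st, ] <- counts[st, ] +
        as.integer(table(factor(ref, levels = c(change_types, "others"))))
      if (st %in% change_types) {
        drv <- vapply(pick, function(p) ledger_driver(scene$events, p), character(1))
        keep <- !is.na(drv)
        if (any(keep)) {
          samples <- rbind(samples, data.frame(
            phase = ph, stratum = st, driver = drv[keep],
            weight = design$weight[r]))
        }
      }
    }
  })

  # post-stratified change accuracy pooled over phases
  w <- tapply(pa$area, pa$stratum, sum)
  w <- w[rownames(counts)] / sum(w)
  acc <- tryCatch(
    post_stratified_estimates(counts, weights = as.numeric(w),
                              total_area = sum(pa$area)),
    error = function(e) list(error = conditionMessage(e), counts = counts))
  drivers <- NULL; trends <- NULL
  if (!is.null(samples)) {
    drivers <- driver_proportions(samples, n_boot = n_boot, seed = seed + 1L,
                                  require_complete = FALSE)
    trends <- tryCatch(driver_trend(drivers$per_phase), error = function(e) NULL)
  }
  list(accuracy = acc, drivers = drivers, trends = trends, design = design)
}

# reference driver of a pixel from the truth event ledger (NA if untouched)
ledger_driver <- function(events, pixel) {
  for (ev in events) if (pixel %in% ev$pixels) return(ev$driver)
  NA_character_
}

# write maps, tables and the manifest of a pipeline run
write_run_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scene <- res$scene
  for (yi in seq_along(scene$years)) {
    g <- matrix(res$maps[yi, ], scene$nrow, scene$ncol, byrow = TRUE)
    write_ascii_grid(g, file.path(out_dir, sprintf("cover_%d.asc", scene$years[yi])))
  }
  write_ascii_grid(scene$dem, file.path(out_dir, "dem.asc"))
  utils::write.csv(res$areas, file.path(out_dir, "areas.csv"), row.names = FALSE)
  utils::write.csv(res$wet_area, file.path(out_dir, "wetland_area.csv"),
                   row.names = FALSE)
  if (!is.null(res$drivers))
    utils::write.csv(res$drivers$cumulative, file.path(out_dir, "drivers.csv"),
                     row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Demo scene configuration file path
#'
#' The bundled 40 x 40 demonstration configuration: a coastal gradient with
#' hurricane losses (one recovering, one permanent), gradual drowning,
#' mangrove encroachment into marsh, a restoration gain, mangrove dieback
#' (recovering and permanent) and a small direct conversion.
#'
#' @return Path to the YAML file.
#' @export
demo_config_path <- function() {
  system.file("extdata", "demo_scene.yaml", package = "tidewetland",
              mustWork = TRUE)
}
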