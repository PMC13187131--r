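test_that("pixel series follows the class curve when never inundated", {
  times <- obs_times(1990, 1993)
  sp <- default_class_spectra()
  # tide always below the pixel surface, no noise: exact seasonal curve
  ser <- simulate_pixel_series(rep(1L, 4), 5, times, rep(-0.2, length(times)),
                               1990, noise_scale = 0)
  expect_equal(ser$nir, as.numeric(class_seasonal(sp$tidal_marsh, times)[, 4]))
  # fully inundated: pure open-water spectrum
  ser2 <- simulate_pixel_series(rep(1L, 4), -2, times, rep(0, length(times)),
                                1990, noise_scale = 0)
  expect_equal(ser2$swir2, as.numeric(class_seasonal(sp$open_water, times)[, 6]))
})

test_that("pixel series is deterministic under a fixed seed", {
  times <- obs_times(1990, 1995)
  h <- tide_heights(default_tide_model(), times)
  a <- simulate_pixel_series(rep(2L, 6), 0.6, times, h, 1990, seed = 7)
  b <- simulate_pixel_series(rep(2L, 6), 0.6, times, h, 1990, seed = 7)
  expect_identical(a, b)
  c <- simulate_pixel_series(rep(2L, 6), 0.6, times, h, 1990, seed = 8)
  expect_false(identical(a$nir, c$nir))
})

test_that("tide confounding inflates the variance of an intertidal pixel", {
  times <- obs_times(1990, 2000)
  h <- tide_heights(default_tide_model(), times)
  wet <- simulate_pixel_series(rep(1L, 11), 0.5, times, h, 1990, noise_scale = 0)
  dry <- simulate_pixel_series(rep(1L, 11), 0.5, times, rep(0, length(times)),
                               1990, noise_scale = 0)
  expect_gt(var(wet$nir), var(dry$nir))
})

small_scene_config <- function(events = list()) {
  scene_config(nrow = 12, ncol = 12, start_year = 2000, end_year = 2010,
               obs_start = 1999.0, obs_end = 2011.0, events = events)
}

test_that("scene truth labels conserve area and honour events", {
  ev <- list(
    event_spec("abrupt", "extreme_weather", 2005.0, "open_water",
               rows = c(2, 3), cols = c(8, 9)),                 # permanent, 4 px
    event_spec("abrupt", "extreme_weather", 2005.0, "open_water",
               rows = c(5, 6), cols = c(8, 9), recovery = 4))   # recovers 2009
  sc <- generate_scene(small_scene_config(ev), seed = 3)
  npx <- sc$nrow * sc$ncol
  # every pixel labeled every year; total area conserved
  expect_true(all(sc$truth %in% wetland_classes()))
  expect_equal(rowSums(matrix(1, nrow(sc$truth), npx) * (sc$truth > 0)),
               rep(npx, length(sc$years)))
  tw <- truth_area_series(sc)
  y2004 <- tw$area_km2[tw$year == 2004]
  y2005 <- tw$area_km2[tw$year == 2005]
  # permanent loss: 4 wetland pixels gone from 2005 onward
  loss_px <- (y2004 - y2005) / (sc$pixel_area / 1e6)
  expect_equal(loss_px, 8)   # both blocks flooded in 2005
  expect_equal(tw$area_km2[tw$year == 2010], y2004 - 4 * sc$pixel_area / 1e6)
  # recovery block restored from 2009
  p <- sc$truth[, (5 - 1) * 12 + 8]     # row 5, col 8 (row-major)
  yrs <- sc$years
  expect_true(all(p[yrs %in% 2005:2008] == wetland_classes()[["open_water"]]))
  expect_equal(p[yrs == 2009], unname(p[yrs == 2004]))
  # ledger marks the recoverable event
  expect_true(sc$events[[2]]$recoverable)
  expect_false(sc$events[[1]]$recoverable)
})

test_that("no events means identical truth maps in every year", {
  sc <- generate_scene(small_scene_config(), seed = 5)
  expect_true(all(apply(sc$truth, 2, function(z) length(unique(z)) == 1)))
})

test_that("scene generation is reproducible and validates events", {
  a <- generate_scene(small_scene_config(), seed = 11)
  b <- generate_scene(small_scene_config(), seed = 11)
  expect_identical(a$refl, b$refl)
  expect_identical(a$truth, b$truth)
  # contradictory overlapping events rejected
  ev <- list(
    event_spec("gradual", "chronic_stressor", 2002, "open_water",
               rows = c(2, 3), cols = c(8, 9), duration = 6),
    event_spec("abrupt", "human_activity", 2004, "tidal_marsh",
               rows = c(3, 4), cols = c(9, 10)))
  expect_error(generate_scene(small_scene_config(ev), seed = 1), "overlap")
  # onset outside span rejected
  expect_error(generate_scene(small_scene_config(list(
    event_spec("abrupt", "human_activity", 1980, "open_water",
               rows = c(2, 2), cols = c(2, 2)))), seed = 1), "span")
  # DEM ceiling honoured
  expect_true(all(a$dem <= a$config$dem_ceiling))
})
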