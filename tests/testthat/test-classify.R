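test_that("spectral indices have their defining zeros", {
  row <- data.frame(blue = 0.05, green = 0.2, red = 0.2, nir = 0.2,
                    swir1 = 0.2, swir2 = 0.1, thermal = 0.5)
  idx <- compute_indices(row)
  expect_equal(idx$ndvi, 0)    # NIR == red
  expect_equal(idx$ndwi, 0)    # green == NIR
  expect_equal(idx$mndwi, 0)   # green == SWIR1
  expect_equal(idx$lswi, 0)    # NIR == SWIR1
  # degenerate denominators stay finite
  z <- compute_indices(data.frame(blue = 0, green = 0, red = 0, nir = 0,
                                  swir1 = 0, swir2 = 0, thermal = 0))
  expect_true(all(is.finite(unlist(z))))
})

test_that("features of a constant series have null dynamics", {
  t <- obs_times(2000, 2004)
  ser <- data.frame(time = t, blue = 0.05, green = 0.07, red = 0.06,
                    nir = 0.35, swir1 = 0.22, swir2 = 0.12, thermal = 0.55,
                    qa = TRUE, tide = tide_heights(default_tide_model(), t))
  f <- segment_features(ser, 1, nrow(ser))
  expect_equal(unname(f["nir_slope"]), 0, tolerance = 1e-8)
  expect_equal(unname(f["nir_cos1"]), 0, tolerance = 1e-8)
  expect_equal(unname(f["ndvi_slope"]), 0, tolerance = 1e-8)
  expect_lt(f["red_rmse"], 1e-10)
  # feature extraction is invariant to observation order
  perm <- sample(nrow(ser))
  f2 <- segment_features(ser[perm, ], 1, nrow(ser))
  expect_equal(f, f2, tolerance = 1e-8)
})

test_that("classifier separates the simulated classes and is deterministic", {
  fx <- demo_classifier()
  tr2 <- training_segments(n_per_class = 10, seed = 77)   # held-out draw
  pred <- predict(fx$clf, as.data.frame(tr2$features))
  acc <- mean(as.character(pred) == as.character(tr2$labels))
  expect_gte(acc, 0.95)
  # same data, same seed: identical model predictions
  clf2 <- train_segment_classifier(fx$train$features, fx$train$labels, seed = 43)
  expect_identical(predict(fx$clf, as.data.frame(tr2$features)),
                   predict(clf2, as.data.frame(tr2$features)))
  expect_error(train_segment_classifier(fx$train$features,
                                        rep("tidal_marsh", nrow(fx$train$features))),
               "2 classes")
})

test_that("pure open-water and stable marsh segments get their classes", {
  fx <- demo_classifier()
  times <- obs_times(1996, 2006)
  h <- tide_heights(default_tide_model(), times)
  water <- simulate_pixel_series(rep(5L, 11), -1.0, times, h, 1996, seed = 3)
  seg <- detect_breaks(water)[[1]]
  lab <- recognize_segment_cover(water, seg, fx$clf)
  expect_equal(lab$mode, "stable")
  expect_equal(lab$class, wetland_classes()[["open_water"]])
  marsh <- simulate_pixel_series(rep(1L, 11), 0.8, times, h, 1996, seed = 4)
  seg2 <- detect_breaks(marsh)[[1]]
  lab2 <- recognize_segment_cover(marsh, seg2, fx$clf)
  expect_equal(lab2$mode, "stable")
  expect_equal(lab2$class, wetland_classes()[["tidal_marsh"]])
})

gradual_series <- function(from, to, t_on, dur, times, elev, seed) {
  sp <- default_class_spectra()
  h <- tide_heights(default_tide_model(), times)
  w <- pmin(pmax((times - t_on) / dur, 0), 1)
  dry <- (1 - w) * class_seasonal(sp[[from]], times) +
    w * class_seasonal(sp[[to]], times)
  f <- pmin(pmax((h - elev) / 0.3, 0), 1)
  refl <- (1 - f) * dry + f * class_seasonal(sp$open_water, times)
  refl <- refl + 0.012 * withr::with_seed(seed,
    matrix(rnorm(length(refl)), nrow(refl)))
  ser <- data.frame(time = times)
  for (j in seq_along(band_names())) ser[[band_names()[j]]] <- refl[, j]
  ser$qa <- TRUE
  ser$tide <- h
  ser
}

test_that("gradual encroachment yields a transitional marsh-to-mangrove label", {
  fx <- demo_classifier()
  times <- obs_times(1996, 2010)
  ser <- gradual_series("tidal_marsh", "mangrove", 2000, 8, times, 0.8, seed = 5)
  segs <- detect_breaks(ser)
  expect_length(segs, 1)   # gradual change absorbed by the segment
  lab <- recognize_segment_cover(ser, segs[[1]], fx$clf)
  expect_equal(lab$mode, "transitional")
  expect_equal(lab$start_class, wetland_classes()[["tidal_marsh"]])
  expect_equal(lab$end_class, wetland_classes()[["mangrove"]])
  expect_true(lab$start_class != lab$end_class)
})

test_that("annual rasterization follows the anchor, gap-fill and apportioning rules", {
  mk_seg <- function(s, e) list(start = s, end = e, first_idx = 1, last_idx = 2,
                                n_obs = 2, ended_by_break = FALSE,
                                break_time = NA, provisional = FALSE, fits = NA)
  stable <- function(cl) list(mode = "stable", class = cl)
  trans <- function(a, b) list(mode = "transitional", start_class = a, end_class = b)
  pr <- list(list(
    segments = list(mk_seg(2000.0, 2004.2), mk_seg(2005.4, 2008.9)),
    labels = list(stable(1L), stable(5L))))
  m <- annual_maps(pr, 1999:2008)
  # before first observation: nodata
  expect_equal(m[1, 1], 0L)
  # anchor inside a stable segment
  expect_equal(m[1999:2008 == 2003, 1], 1L)
  # anchor in the post-break gap (2004.5): previous segment's label
  expect_equal(m[1999:2008 == 2004, 1], 1L)
  expect_equal(m[1999:2008 == 2006, 1], 5L)
  # transitional apportioning over 2000-2008: 2001 start class, 2007 end class
  pr2 <- list(list(segments = list(mk_seg(2000.0, 2008.0)),
                   labels = list(trans(1L, 2L))))
  m2 <- annual_maps(pr2, 2000:2008)
  expect_equal(m2[2000:2008 == 2001, 1], 1L)
  expect_equal(m2[2000:2008 == 2007, 1], 2L)
})
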