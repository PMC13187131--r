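#' Segment features for classification
#'
#' The feature vector of a temporal segment: for each of the twelve sources
#' (seven bands and five indices), the harmonic-fit coefficients and RMSE --
#' level (intercept evaluated at `eval_time`), slope, annual cosine/sine,
#' tide coefficient (0 when absent) and RMSE. With `window = TRUE` the slope
#' is zeroed so a window snapshot of a drifting segment resembles the stable
#' training examples of the cover it is passing through.
#'
#' @param series Prepped observation data frame.
#' @param first_idx,last_idx Observation range of the segment.
#' @param eval_time Time (decimal years) at which the level is evaluated;
#'   defaults to the segment midpoint.
#' @param order Annual harmonic order (fixed at fit time).
#' @param tide_enabled Use the water-level covariate.
#' @param window Zero the slope entries (window snapshot).
#' @return Named numeric vector of length `12 * 6` (order 1).
#' @export
segment_features <- function(series, first_idx, last_idx, eval_time = NULL,
                             order = 1, tide_enabled = TRUE, window = FALSE) {
  idx <- first_idx:last_idx
  s <- compute_indices(series[idx, , drop = FALSE])
  sources <- c(band_names(), index_names())
  tide <- if (tide_enabled) s$tide else NULL
  fit <- fit_harmonic_y(s$time, as.matrix(s[sources]), tide, order = order)
  eval_time <- eval_time %||% mean(range(s$time))
  cn <- fit$colnames
  feats <- numeric(0)
  for (j in seq_along(sources)) {
    cf <- stats::setNames(fit$coef[, j], cn)
    level <- cf[["a0"]] + cf[["a1"]] * (eval_time - fit$t0)
    slope <- if (window) 0 else cf[["a1"]]
    v <- c(level = level, slope = slope,
           cos1 = cf[["c1"]], sin1 = cf[["s1"]],
           tide = if ("c_tide" %in% cn) cf[["c_tide"]] else 0,
           rmse = unname(fit$rmse[j]))
    names(v) <- paste(sources[j], names(v), sep = "_")
    feats <- c(feats, v)
  }
  feats
}

#' Build a training set of stable segments from the simulator
#'
#' Simulates stable single-class pixels across class-typical elevations and
#' extracts whole-segment features, standing in for an interpreted training
#' corpus. "Other" is represented by its two subclasses (upland vegetation,
#' developed/barren) and merged at map output.
#'
#' @param n_per_class Simulated pixels per trained class.
#' @param spectra Class spectra.
#' @param tide A [tide_model()].
#' @param years Span of the simulated series (calendar years).
#' @param noise_scale Noise multiplier.
#' @param d_full Full-inundation depth (m).
#' @param seed Seed.
#' @return List with `features` (matrix) and `labels` (factor of trained
#'   class names).
#' @export
training_segments <- function(n_per_class = 50, spectra = default_class_spectra(),
                              tide = default_tide_model(),
                              years = 1985:1994, noise_scale = 1, d_full = 0.3,
                              seed = 1L) {
  elev_range <- list(
    tidal_marsh = c(0.4, 1.1), mangrove = c(0.4, 1.1), tidal_flat = c(-0.35, 0.3),
    mangrove_dieback = c(0.4, 1.1), open_water = c(-1.4, -0.5),
    upland_vegetation = c(1.6, 2.4), developed_barren = c(1.6, 2.4))
  classes <- names(elev_range)
  times <- seq(years[1], years[length(years)] + 0.999, by = 32 / 365.25)
  feats <- NULL; labels <- character(0)
  ny <- length(years)
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    code <- target_code(cl)
    for (k in seq_len(n_per_class)) {
      sd_k <- seed + 1000L * ci + k
      elev <- withr::with_seed(sd_k, stats::runif(1, elev_range[[cl]][1],
                                                  elev_range[[cl]][2]))
      ser <- simulate_pixel_series(rep(code, ny), elev, times, tide,
                                   start_year = years[1], spectra = spectra,
                                   d_full = d_full, noise_scale = noise_scale,
                                   seed = sd_k)
      f <- segment_features(ser, 1, nrow(ser))
      feats <- rbind(feats, f)
      labels <- c(labels, cl)
    }
  }
  rownames(feats) <- NULL
  list(features = feats, labels = factor(labels, levels = classes))
}

#' Train the segment cover classifier
#'
#' A seeded random-forest ensemble over segment features with
#' class-probability output; reproducible under a fixed seed.
#'
#' @param features Feature matrix (rows = segments).
#' @param labels Factor of class names (>= 2 classes present).
#' @param seed Seed.
#' @param ntree Number of trees.
#' @return A `randomForest` classifier.
#' @export
train_segment_classifier <- function(features, labels, seed = 1L, ntree = 300) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stopf("training set must contain at least 2 classes")
  withr::with_seed(seed,
    randomForest::randomForest(x = as.data.frame(features), y = labels,
                               ntree = ntree))
}

# predicted trained-class name for a feature vector, merged to legend code
classify_features <- function(classifier, feats) {
  cl <- as.character(stats::predict(classifier,
                                    newdata = as.data.frame(t(feats))))
  merged_code(target_code(cl))
}

#' Recognize the cover of a temporal segment
#'
#' Applies the segment-cover-recognition rule: classify window snapshots at
#' the segment's first and last year; if the two labels agree (after merging
#' "other" subclasses), or no detection band shows a significant
#' within-segment slope, the segment is stable and labeled from its
#' whole-segment features; otherwise it is transitional from the start label
#' to the end label (a gradual, irreversible conversion such as marsh
#' drowning or mangrove encroachment).
#'
#' @param series Prepped observation data frame for the pixel.
#' @param segment One segment from [detect_breaks()].
#' @param classifier Trained classifier ([train_segment_classifier()]).
#' @param params The [break_params()] used at detection (detection bands and
#'   tide setting are reused here).
#' @param alpha Significance level of the slope test.
#' @return A `segment_label`: list with `mode` ("stable"/"transitional"),
#'   and `class` or `start_class`/`end_class` (legend codes).
#' @export
recognize_segment_cover <- function(series, segment, classifier,
                                    params = break_params(), alpha = 0.05) {
  i1 <- segment$first_idx; i2 <- segment$last_idx
  span <- series$time[i2] - series$time[i1]
  whole <- function() {
    f <- segment_features(series, i1, i2, tide_enabled = params$tide_enabled)
    list(mode = "stable", class = classify_features(classifier, f))
  }
  if (span < 2 || segment$n_obs < 2 * params$min_obs_init) return(whole())
  # window snapshots: first and last year of the segment
  t_start <- series$time[i1] + 0.5
  t_end <- series$time[i2] - 0.5
  f_start <- segment_features(series, i1, i2, eval_time = t_start,
                              tide_enabled = params$tide_enabled, window = TRUE)
  f_end <- segment_features(series, i1, i2, eval_time = t_end,
                            tide_enabled = params$tide_enabled, window = TRUE)
  lab_start <- classify_features(classifier, f_start)
  lab_end <- classify_features(classifier, f_end)
  if (lab_start == lab_end) return(whole())
  if (!slope_significant(series, segment, params, alpha)) return(whole())
  list(mode = "transitional", start_class = lab_start, end_class = lab_end)
}

# any detection band with a significant linear slope inside the segment?
slope_significant <- function(series, segment, params, alpha = 0.05) {
  fit <- segment$fits
  if (is.null(fit)) return(FALSE)
  bands <- match(params$detect_bands, band_names())
  a1 <- fit$coef["a1", bands]
  se <- fit$se["a1", bands]
  df <- fit$n - nrow(fit$coef)
  if (df <= 0) return(FALSE)
  p <- 2 * stats::pt(-abs(a1 / pmax(se, 1e-12)), df)
  any(p < alpha)
}

#' Rasterize labeled segments into annual maps
#'
#' The label of a pixel-year is the label holding at the anchor date July 1.
#' Stable segments contribute their class; transitional segments contribute
#' the start class for anchors in the first half of the segment span and the
#' end class thereafter (linear apportioning). Anchors falling in a
#' post-break gap carry the last closed segment's (end) label forward;
#' anchors before the first segment are nodata (0).
#'
#' @param pixel_results List over pixels (row-major); each element has
#'   `segments` and `labels` (parallel lists).
#' @param years Calendar years to rasterize.
#' @return Integer matrix `length(years) x n_pixels` of legend codes.
#' @export
annual_maps <- function(pixel_results, years) {
  anchors <- years + 0.5
  npx <- length(pixel_results)
  out <- matrix(0L, length(years), npx)
  for (p in seq_len(npx)) {
    segs <- pixel_results[[p]]$segments
    labs <- pixel_results[[p]]$labels
    if (!length(segs)) next
    for (yi in seq_along(anchors)) {
      a <- anchors[yi]
      code <- 0L
      for (si in seq_along(segs)) {
        sg <- segs[[si]]; lb <- labs[[si]]
        if (is.null(lb)) next
        if (a < sg$start) break
        if (a <= sg$end) {
          code <- label_at(lb, (a - sg$start) / max(sg$end - sg$start, 1e-9))
          break
        }
        code <- label_at(lb, 1)   # past this segment: carry end label forward
      }
      out[yi, p] <- code
    }
  }
  out
}

# label of a segment at a relative position in [0, 1]
label_at <- function(label, frac) {
  if (label$mode == "stable") label$class
  else if (frac < 0.5) label$start_class else label$end_class
}
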