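#' Disturbance / transition event specification
#'
#' Describes one cover-change event applied to a rectangular block of pixels.
#' Abrupt events (hurricane or freeze analogues, dredge-and-fill, restoration
#' breaches) switch the cover at `onset`, optionally reverting to the prior
#' cover after `recovery` years. Gradual events (drowning under relative sea
#' level rise, mangrove encroachment into marsh) blend the reflectance from
#' the prior cover to `target` over `duration` years; the truth label flips
#' at the interpolated transition year (the midpoint of the ramp).
#'
#' @param kind "abrupt" or "gradual".
#' @param driver One of "extreme_weather", "human_activity", "chronic_stressor".
#' @param onset Decimal year of onset.
#' @param target Target class name (see [wetland_classes()]; training
#'   subclasses allowed).
#' @param rows,cols Integer ranges of affected rows/columns.
#' @param recovery Years until the prior cover is restored (abrupt only;
#'   `NULL` = permanent).
#' @param duration Transition length in years (gradual only, > 0).
#' @param only_from Optional class name: restrict the affected set to pixels
#'   holding that cover at onset.
#' @return An object of class `event_spec`.
#' @export
event_spec <- function(kind, driver, onset, target, rows, cols,
                       recovery = NULL, duration = NULL, only_from = NULL) {
  kind <- match.arg(kind, c("abrupt", "gradual"))
  driver <- match.arg(driver, c("extreme_weather", "human_activity", "chronic_stressor"))
  if (kind == "gradual") {
    if (is.null(duration) || duration <= 0) stopf("gradual events need duration > 0")
    if (!is.null(recovery)) stopf("gradual events do not take a recovery time")
  }
  structure(list(kind = kind, driver = driver, onset = onset, target = target,
                 rows = range(rows), cols = range(cols),
                 recovery = recovery, duration = duration,
                 only_from = only_from),
            class = "event_spec")
}

# temporal window during which an event "owns" its pixels (for overlap checks)
event_window <- function(ev) {
  if (ev$kind == "gradual") c(ev$onset, ev$onset + ev$duration)
  else if (!is.null(ev$recovery)) c(ev$onset, ev$onset + ev$recovery)
  else c(ev$onset, ev$onset)      # permanent switch is instantaneous
}

#' Scene configuration
#'
#' Assembles the configuration for [generate_scene()]. Defaults describe a
#' 40 x 40 pixel coastal gradient (~1.4 km square at 30 m pixels): open water
#' on the seaward side, tidal flat near mean sea level, a vegetated
#' intertidal platform (mangrove at southern latitudes, tidal marsh
#' elsewhere), and upland "other" cover landward. Observations follow a
#' 32-day cadence over 1984.0-2024.25 with random cloud gaps.
#'
#' @param nrow,ncol Grid dimensions.
#' @param start_year,end_year First/last mapped calendar year.
#' @param obs_start,obs_end Observation span, decimal years.
#' @param cadence_days Observation cadence (days).
#' @param clear_prob Probability an observation is clear (cloud-gap model).
#' @param d_full Water depth above the pixel surface (m) at which the pixel
#'   reads as fully open water; inundated fraction ramps linearly from 0 at
#'   the surface to 1 at this depth.
#' @param noise_scale Multiplier on class noise sd (0 = noiseless).
#' @param tide A [tide_model()]; default mixes semidiurnal constituents with
#'   an annual and a multi-year sea-level anomaly term.
#' @param tide_valid_max_elev Pixels above this elevation (m) lack water-level
#'   predictions and inherit the nearest valid pixel's at prep time.
#' @param dem_ceiling Coastal elevation ceiling (m); DEM is clipped to it.
#' @param lat_range North/south latitude bounds mapped onto rows (degrees N).
#' @param mangrove_lat_max Latitude below which intertidal vegetation is
#'   mangrove instead of marsh.
#' @param events List of [event_spec()] objects.
#' @param spectra Class spectra, see [default_class_spectra()].
#' @return A `scene_config` list.
#' @export
scene_config <- function(nrow = 40, ncol = 40,
                         start_year = 1985, end_year = 2023,
                         obs_start = 1984.0, obs_end = 2024.25,
                         cadence_days = 32, clear_prob = 0.8,
                         d_full = 0.3, noise_scale = 1,
                         tide = default_tide_model(),
                         tide_valid_max_elev = Inf,
                         dem_ceiling = 10,
                         lat_range = c(31, 25), mangrove_lat_max = 27.5,
                         events = list(),
                         spectra = NULL) {
  spectra <- spectra %||% default_class_spectra(noise_scale = 1)
  structure(list(nrow = nrow, ncol = ncol, start_year = start_year,
                 end_year = end_year, obs_start = obs_start, obs_end = obs_end,
                 cadence_days = cadence_days, clear_prob = clear_prob,
                 d_full = d_full, noise_scale = noise_scale, tide = tide,
                 tide_valid_max_elev = tide_valid_max_elev,
                 dem_ceiling = dem_ceiling, lat_range = lat_range,
                 mangrove_lat_max = mangrove_lat_max,
                 events = events, spectra = spectra),
            class = "scene_config")
}

#' @rdname scene_config
#' @export
default_tide_model <- function() {
  tide_model(0, data.frame(
    # M2, S2 semidiurnal; K1 diurnal; annual; multi-year sea-level anomaly
    amplitude = c(0.50, 0.15, 0.10, 0.08, 0.06),
    period    = c(0.5175251, 0.5, 0.9972696, 365.25, 1168.8),
    phase     = c(0, 1.1, 2.3, 0.7, 0.4)))
}

# smooth random field via repeated 3x3 mean filtering of white noise
smooth_field <- function(nr, nc, passes = 4) {
  m <- matrix(stats::rnorm(nr * nc), nr, nc)
  for (p in seq_len(passes)) {
    padded <- m[c(1, 1:nr, nr), c(1, 1:nc, nc)]
    acc <- matrix(0, nr, nc)
    for (dr in 0:2) for (dc in 0:2) acc <- acc + padded[dr + 1:nr, dc + 1:nc]
    m <- acc / 9
  }
  m / stats::sd(m)
}

# inundated fraction: linear ramp in water depth above the surface
inundation_fraction <- function(tide, elevation, d_full) {
  clip01((tide - elevation) / d_full)
}

#' Simulate one pixel's observation series
#'
#' Builds a tide-confounded multiband series for a pixel whose cover follows
#' `trajectory` (one class label per calendar year). When the water level is
#' at or below the pixel surface the reflectance is the class seasonal value
#' plus noise; when above, the signal is mixed linearly towards the open
#' water spectrum by the inundated fraction
#' `f = clip((tide - elevation) / d_full, 0, 1)`.
#'
#' @param trajectory Integer class codes, one per year starting at
#'   `start_year` (see [wetland_classes()]).
#' @param elevation Pixel surface elevation (m).
#' @param times Observation times, decimal years; must fall within the years
#'   covered by `trajectory`.
#' @param tide Water-level heights at `times` (m), or a [tide_model()].
#' @param start_year Calendar year of `trajectory[1]`.
#' @param spectra Class spectra list.
#' @param d_full Full-inundation depth (m).
#' @param noise_scale Multiplier on class noise sd (0 = noiseless).
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @return Data frame with columns `time`, the seven bands, `qa` (clear flag)
#'   and `tide`.
#' @export
simulate_pixel_series <- function(trajectory, elevation, times, tide,
                                  start_year, spectra = default_class_spectra(),
                                  d_full = 0.3, noise_scale = 1, seed = 1L) {
  bn <- band_names()
  if (inherits(tide, "tide_model")) tide <- tide_heights(tide, times)
  stopifnot(length(tide) == length(times))
  empty <- data.frame(time = numeric(0))
  for (b in bn) empty[[b]] <- numeric(0)
  empty$qa <- logical(0); empty$tide <- numeric(0)
  if (!length(times)) return(empty)
  yr_idx <- floor(times) - start_year + 1L
  if (any(yr_idx < 1L | yr_idx > length(trajectory)))
    stopf("trajectory does not cover the observation span")
  dry <- matrix(0, length(times), 7)
  sds <- matrix(0, length(times), 7)
  for (code in unique(trajectory[yr_idx])) {
    sel <- trajectory[yr_idx] == code
    sp <- spec_for_code(spectra, code)
    dry[sel, ] <- class_seasonal(sp, times[sel])
    sds[sel, ] <- rep(sp$noise_sd, each = sum(sel))
  }
  wsp <- spectra$open_water
  wet <- class_seasonal(wsp, times)
  f <- inundation_fraction(tide, elevation, d_full)
  refl <- (1 - f) * dry + f * wet
  sdm <- (1 - f) * sds + f * rep(wsp$noise_sd, each = length(times))
  if (noise_scale > 0) {
    noise <- withr::with_seed(seed,
      matrix(stats::rnorm(length(refl)), nrow(refl), ncol(refl)))
    refl <- refl + noise_scale * sdm * noise
  }
  out <- data.frame(time = times)
  for (j in seq_along(bn)) out[[bn[j]]] <- refl[, j]
  out$qa <- TRUE
  out$tide <- tide
  out
}

#' Generate a synthetic coastal scene
#'
#' Produces the full simulated study system: a DEM along a seaward-landward
#' gradient, per-pixel tide-confounded observation stacks with cloud gaps,
#' per-pixel-per-year truth labels, and a truth event ledger recording every
#' disturbance with its driver. Regenerating with the same config and seed
#' reproduces the scene exactly.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed.
#' @return An object of class `wet_scene` with elements `nrow`, `ncol`,
#'   `dem` (matrix, m), `lat` (per-row degrees N), `times`, `refl`
#'   (array time x band x pixel, pixels in row-major order), `clear`
#'   (time x pixel logical), `tide` (time x pixel heights, `NA` where the
#'   water-level model has no coverage), `truth` (year x pixel class codes),
#'   `years`, `events` (truth ledger), `config`, `seed`.
#' @export
generate_scene <- function(config, seed = 1L) {
  stopifnot(inherits(config, "scene_config"))
  cf <- config
  nr <- cf$nrow; nc <- cf$ncol; npx <- nr * nc
  bn <- band_names()
  codes <- wetland_classes(); sub <- other_subclasses()

  withr::with_seed(seed, {
    # --- DEM: seaward->landward gradient plus smooth relief, clipped
    grad <- seq(-1.2, 2.2, length.out = nc)
    dem <- outer(rep(1, nr), grad) + 0.08 * smooth_field(nr, nc)
    dem <- pmin(dem, cf$dem_ceiling)
    lat <- seq(cf$lat_range[1], cf$lat_range[2], length.out = nr)

    # --- base cover from elevation and latitude
    base <- matrix(sub[["upland_vegetation"]], nr, nc)
    lat_m <- matrix(lat, nr, nc)
    # zonation: vegetated platform sits in the upper intertidal (above ~40%
    # of the high-tide range here); lower lies the unvegetated flat
    base[dem < -0.4] <- codes[["open_water"]]
    base[dem >= -0.4 & dem < 0.35] <- codes[["tidal_flat"]]
    veg <- dem >= 0.35 & dem < 1.2
    base[veg] <- ifelse(lat_m[veg] < cf$mangrove_lat_max,
                        codes[["mangrove"]], codes[["tidal_marsh"]])
    base[dem >= 1.2 & dem < 1.6] <- codes[["tidal_marsh"]] # high marsh fringe
    # scatter some developed/barren upland
    upl <- which(dem >= 1.6)
    if (length(upl) > 8) {
      dev_px <- sample(upl, max(1L, length(upl) %/% 5))
      base[dev_px] <- sub[["developed_barren"]]
    }

    # --- observation times, cloud gaps, tide
    times <- seq(cf$obs_start, cf$obs_end, by = cf$cadence_days / 365.25)
    nt <- length(times)
    clear <- matrix(stats::runif(nt * npx) < cf$clear_prob, nt, npx)
    heights <- tide_heights(cf$tide, times)
    valid <- as.vector(t(dem <= cf$tide_valid_max_elev))   # row-major
    tide_mx <- matrix(rep(heights, npx), nt, npx)
    tide_mx[, !valid] <- NA_real_

    # --- resolve events to pixel sets and validate
    years <- cf$start_year:cf$end_year
    ny <- length(years)
    events <- lapply(cf$events, function(ev) {
      stopifnot(inherits(ev, "event_spec"))
      if (ev$onset < cf$obs_start || ev$onset > cf$obs_end)
        stopf("event onset %.2f outside the simulated span", ev$onset)
      if (any(ev$rows < 1 | ev$rows > nr | ev$cols < 1 | ev$cols > nc))
        stopf("event block outside the grid")
      rc <- expand.grid(row = ev$rows[1]:ev$rows[2], col = ev$cols[1]:ev$cols[2])
      ev$pixels <- px_index(rc$row, rc$col, nc)
      ev$target_code <- target_code(ev$target)
      ev
    })
    check_event_overlaps(events)

    # --- per-pixel dry spectra, truth labels, mixing, noise
    anchors <- years + 0.5
    refl <- array(NA_real_, dim = c(nt, 7, npx))
    truth <- matrix(0L, ny, npx)
    wsp <- cf$spectra$open_water
    wet <- class_seasonal(wsp, times)
    wet_sd <- matrix(rep(wsp$noise_sd, each = nt), nt, 7)
    ev_by_px <- events_by_pixel(events, npx)
    from_codes <- lapply(events, function(e) integer(0))

    for (p in seq_len(npx)) {
      rc <- px_rowcol(p, nc)
      code0 <- base[rc[1, "row"], rc[1, "col"]]
      sp0 <- spec_for_code(cf$spectra, code0)
      dry <- class_seasonal(sp0, times)
      sds <- matrix(rep(sp0$noise_sd, each = nt), nt, 7)
      lab <- rep(merged_code(code0), ny)
      cur <- code0
      for (ei in ev_by_px[[p]]) {
        ev <- events[[ei]]
        from_codes[[ei]][match(p, events[[ei]]$pixels)] <- merged_code(cur)
        tsp <- spec_for_code(cf$spectra, ev$target_code)
        tgt <- class_seasonal(tsp, times)
        tgt_sd <- matrix(rep(tsp$noise_sd, each = nt), nt, 7)
        if (ev$kind == "abrupt") {
          if (is.null(ev$recovery)) {
            sel <- times >= ev$onset
            lab_sel <- anchors >= ev$onset
            cur <- ev$target_code
          } else {
            sel <- times >= ev$onset & times < ev$onset + ev$recovery
            lab_sel <- anchors >= ev$onset & anchors < ev$onset + ev$recovery
          }
          dry[sel, ] <- tgt[sel, ]
          sds[sel, ] <- tgt_sd[sel, ]
          lab[lab_sel] <- merged_code(ev$target_code)
        } else {
          w <- clip01((times - ev$onset) / ev$duration)
          dry <- (1 - w) * dry + w * tgt
          sds <- (1 - w) * sds + w * tgt_sd
          lab[anchors >= ev$onset + ev$duration / 2] <- merged_code(ev$target_code)
          cur <- ev$target_code
        }
      }
      elev <- dem[rc[1, "row"], rc[1, "col"]]
      f <- inundation_fraction(heights, elev, cf$d_full)
      obs <- (1 - f) * dry + f * wet
      sdm <- (1 - f) * sds + f * wet_sd
      if (cf$noise_scale > 0) {
        obs <- obs + cf$noise_scale * sdm *
          matrix(stats::rnorm(nt * 7), nt, 7)
      }
      refl[, , p] <- obs
      truth[, p] <- lab
    }

    ledger <- lapply(seq_along(events), function(i) {
      ev <- events[[i]]
      list(kind = ev$kind, driver = ev$driver, onset = ev$onset,
           target = ev$target, recovery = ev$recovery, duration = ev$duration,
           recoverable = (ev$kind == "abrupt" && !is.null(ev$recovery)),
           pixels = ev$pixels, from = from_codes[[i]])
    })

    structure(list(nrow = nr, ncol = nc, pixel_area = PIXEL_AREA_M2,
                   dem = dem, lat = lat, base = base,
                   times = times, refl = refl, clear = clear,
                   tide = tide_mx, tide_valid = valid,
                   tide_model = cf$tide,
                   years = years, truth = truth, events = ledger,
                   config = cf, seed = seed),
              class = "wet_scene")
  })
}

# class name -> simulation code (subclasses allowed)
target_code <- function(name) {
  all_codes <- c(wetland_classes(), other_subclasses())
  if (!name %in% names(all_codes)) stopf("unknown class '%s'", name)
  unname(all_codes[[name]])
}

# subclass codes collapse to the "other" legend code
merged_code <- function(code) if (code %in% other_subclasses()) wetland_classes()[["other"]] else code

# indices of events affecting each pixel, in onset order
events_by_pixel <- function(events, npx) {
  out <- vector("list", npx)
  ord <- order(vapply(events, function(e) e$onset, numeric(1)))
  for (ei in ord) for (p in events[[ei]]$pixels) out[[p]] <- c(out[[p]], ei)
  out
}

check_event_overlaps <- function(events) {
  n <- length(events)
  if (n < 2) return(invisible())
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!length(intersect(events[[i]]$pixels, events[[j]]$pixels))) next
    wi <- event_window(events[[i]]); wj <- event_window(events[[j]])
    if (wi[1] <= wj[2] && wj[1] <= wi[2])
      stopf("events %d and %d overlap in time on shared pixels", i, j)
  }
  invisible()
}

#' Extract one pixel's observation series from a scene
#'
#' @param scene A `wet_scene`.
#' @param row,col Pixel coordinates.
#' @return Data frame with `time`, seven band columns, `qa` and `tide`
#'   (`NA` tide where the water-level model has no coverage; see
#'   [attach_tide()]).
#' @export
scene_pixel_series <- function(scene, row, col) {
  p <- px_index(row, col, scene$ncol)
  bn <- band_names()
  out <- data.frame(time = scene$times)
  for (j in seq_along(bn)) out[[bn[j]]] <- scene$refl[, j, p]
  out$qa <- scene$clear[, p]
  out$tide <- scene$tide[, p]
  attr(out, "pixel") <- c(row = row, col = col)
  out
}

#' Truth class areas per year
#'
#' @param scene A `wet_scene`.
#' @param classes Class codes to count (default: wetland extent classes).
#' @return Data frame `year`, `area_km2` summed over `classes`.
#' @export
truth_area_series <- function(scene, classes = wetland_extent_classes()) {
  cnt <- apply(scene$truth, 1, function(z) sum(z %in% classes))
  data.frame(year = scene$years, area_km2 = cnt * scene$pixel_area / 1e6)
}
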