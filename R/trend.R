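#' Sen's slope with rank-based confidence interval
#'
#' The Theil-Sen estimator: the median of all pairwise slopes
#' `(x_j - x_i)/(j - i)`, `i < j`. The confidence interval uses the
#' rank-based procedure driven by the Mann-Kendall variance (Gilbert): with
#' `N'` pairwise slopes and `C = z_{1-alpha/2} * sqrt(VarS)`, the bounds are
#' the slopes of rank `(N' - C)/2` and `(N' + C)/2 + 1`.
#'
#' @param x Numeric series (annual values, no gaps); n >= 3.
#' @param times Optional time coordinates (defaults to `1:n`).
#' @param conf Confidence level.
#' @return List: `slope`, `ci` (length 2), `n_pairs`.
#' @export
#' @examples
#' sen_slope(c(1, 2, 3, 4))$slope   # 1
sen_slope <- function(x, times = seq_along(x), conf = 0.95) {
  ok <- !is.na(x)
  x <- x[ok]; times <- times[ok]
  n <- length(x)
  if (n < 3) stopf("sen_slope needs at least 3 non-missing values")
  ij <- utils::combn(n, 2)
  slopes <- (x[ij[2, ]] - x[ij[1, ]]) / (times[ij[2, ]] - times[ij[1, ]])
  slopes <- sort(slopes)
  np <- length(slopes)
  vs <- mk_var_s(x)
  C <- stats::qnorm(1 - (1 - conf) / 2) * sqrt(vs)
  lo <- max(1L, floor((np - C) / 2) + 1L)
  hi <- min(np, ceiling((np + C) / 2))
  if (lo > hi) lo <- hi <- (np + 1L) %/% 2L   # degenerate band: collapse to median

  list(slope = stats::median(slopes), ci = c(slopes[lo], slopes[hi]),
       n_pairs = np)
}

# tie-corrected Mann-Kendall variance of S
mk_var_s <- function(x) {
  n <- length(x)
  ties <- table(x)
  (n * (n - 1) * (2 * n + 5) - sum(ties * (ties - 1) * (2 * ties + 5))) / 18
}

#' Mann-Kendall trend test
#'
#' `S = sum_{i<j} sign(x_j - x_i)`; the variance carries the tie correction
#' `VarS = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18`; `Z` applies the +/-1
#' continuity correction; the two-sided p-value is normal-approximate.
#'
#' @param x Numeric series, n >= 3.
#' @param alpha Significance level (two-sided).
#' @return List: `S`, `var_s`, `Z`, `p`, `significant`.
#' @export
#' @examples
#' mann_kendall(1:5)$S   # 10
mann_kendall <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stopf("mann_kendall needs at least 3 non-missing values")
  ij <- utils::combn(n, 2)
  S <- sum(sign(x[ij[2, ]] - x[ij[1, ]]))
  vs <- mk_var_s(x)
  Z <- if (vs == 0) 0 else if (S > 0) (S - 1) / sqrt(vs)
       else if (S < 0) (S + 1) / sqrt(vs) else 0
  p <- 2 * stats::pnorm(-abs(Z))
  list(S = S, var_s = vs, Z = Z, p = p, significant = (vs > 0 && p < alpha))
}

#' Moving-window trend strength (acceleration / deceleration)
#'
#' Sen's slope is computed within each sliding window of `window` years
#' (step one year; a 39-year series yields 30 ten-year windows), then a
#' second-level Sen's slope and Mann-Kendall test are applied to the window
#' slopes. Negative strength means accelerating loss or decelerating gain;
#' positive means the reverse.
#'
#' @param x Annual series; `length(x) >= window + 2`.
#' @param window Window length in years.
#' @param alpha Significance level.
#' @return List: `strength` (units of x per year^2), `ci`, `p`,
#'   `significant`, `window_slopes`.
#' @export
trend_strength <- function(x, window = 10, alpha = 0.05) {
  n <- length(x)
  if (n < window + 2) stopf("series too short for window of %d", window)
  nw <- n - window + 1
  ws <- vapply(seq_len(nw), function(i) {
    sen_slope(x[i:(i + window - 1)])$slope
  }, numeric(1))
  s <- sen_slope(ws)
  mk <- mann_kendall(ws, alpha = alpha)
  list(strength = s$slope, ci = s$ci, p = mk$p, significant = mk$significant,
       window_slopes = ws)
}

#' Full two-level trend analysis of an area series
#'
#' @param x Annual areas (km^2).
#' @param window Moving-window length; strength is skipped (`NA`) when the
#'   series is shorter than `window + 2`.
#' @param alpha Significance level.
#' @return A `trend_result` list: Sen slope + CI, MK statistics, strength +
#'   significance, and the nine-state `symbol` from [classify_zone_trend()].
#' @export
trend_analysis <- function(x, window = 10, alpha = 0.05) {
  s <- sen_slope(x)
  mk <- mann_kendall(x, alpha = alpha)
  st <- if (length(x) >= window + 2) trend_strength(x, window, alpha)
        else list(strength = NA_real_, ci = c(NA_real_, NA_real_),
                  p = NA_real_, significant = FALSE)
  res <- list(slope = s$slope, slope_ci = s$ci, S = mk$S, var_s = mk$var_s,
              Z = mk$Z, p = mk$p, significant = mk$significant,
              strength = st$strength, strength_ci = st$ci,
              strength_p = st$p, strength_significant = st$significant)
  res$symbol <- classify_zone_trend(res)
  structure(res, class = "trend_result")
}

#' Nine-state trend symbol
#'
#' Primary state from the sign of a significant Sen slope (else "none");
#' the acceleration annotation applies only when the strength is
#' MK-significant. Sign semantics: for a loss trend, negative strength means
#' accelerating loss; for a gain trend, negative strength means decelerating
#' gain.
#'
#' @param res A `trend_result` (or compatible list).
#' @return One of "loss"/"gain"/"none" with suffix "_accelerating",
#'   "_decelerating" or "" (not significant / primary "none").
#' @export
classify_zone_trend <- function(res) {
  if (!isTRUE(res$significant)) return("none")
  primary <- if (res$slope < 0) "loss" else "gain"
  if (!isTRUE(res$strength_significant) || is.na(res$strength)) return(primary)
  ann <- if (primary == "loss") {
    if (res$strength < 0) "accelerating" else "decelerating"
  } else {
    if (res$strength > 0) "accelerating" else "decelerating"
  }
  paste(primary, ann, sep = "_")
}

#' Aggregate annual maps into area series by zone and class
#'
#' Areas are pixel counts times the pixel area, in km^2. Zones may be an
#' integer zone raster (subbasin-style units) or a binning specification on
#' a static per-pixel value (DEM elevation or latitude):
#' `list(values = <per-pixel numeric>, from, to, by)` with half-open bins
#' `[lo, hi)`.
#'
#' @param maps Integer matrix `n_years x n_pixels`.
#' @param years Calendar years.
#' @param zones `NULL` (one zone), an integer vector of zone ids per pixel,
#'   or a bin spec list.
#' @param classes Named integer vector of class codes to tabulate.
#' @param pixel_area_m2 Pixel area.
#' @return Data frame `zone`, `class`, `year`, `area_km2`.
#' @export
aggregate_areas <- function(maps, years, zones = NULL,
                            classes = wetland_classes(),
                            pixel_area_m2 = PIXEL_AREA_M2) {
  npx <- ncol(maps)
  if (is.null(zones)) {
    zid <- rep(1L, npx); zlev <- 1L
  } else if (is.list(zones)) {
    edges <- seq(zones$from, zones$to, by = zones$by)
    if (length(zones$values) != npx) stopf("bin values do not match the map grid")
    zid <- findInterval(zones$values, edges, rightmost.closed = FALSE)
    zid[zones$values >= zones$to | zones$values < zones$from] <- NA_integer_
    zlev <- seq_len(length(edges) - 1)
  } else {
    if (length(zones) != npx) stopf("zone raster does not match the map grid")
    zid <- as.integer(zones); zlev <- sort(unique(zid[!is.na(zid)]))
  }
  out <- expand.grid(zone = zlev, class = names(classes), year = years,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$area_km2 <- 0
  key <- paste(out$zone, out$class, out$year)
  for (yi in seq_along(years)) {
    lab <- maps[yi, ]
    for (ci in seq_along(classes)) {
      sel <- lab == classes[ci] & !is.na(zid)
      if (!any(sel)) next
      cnt <- table(zid[sel])
      k <- paste(names(cnt), names(classes)[ci], years[yi])
      out$area_km2[match(k, key)] <- as.numeric(cnt) * pixel_area_m2 / 1e6
    }
  }
  out
}

#' Bin edges helper for migration analyses
#'
#' @param from,to,by Bin specification; e.g. elevation -1 to 2 m by 0.1 m
#'   gives 30 bins, latitude 25 to 31 degrees by 0.5 gives 12 bins.
#' @return Number of half-open bins.
#' @export
n_bins <- function(from, to, by) length(seq(from, to, by = by)) - 1L
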