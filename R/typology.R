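#' Classify a pixel's annual label trajectory
#'
#' Partitions trajectories into the change strata: `stable` (no label change
#' at all), `permanent_loss` (wetland at the start, non-wetland at the end,
#' not re-established by the final year or any guard year), `permanent_gain`
#' (the reverse), `fluctuation` (temporary wetland loss/gain, or any
#' wetland-to-wetland internal transition such as mangrove encroachment of
#' marsh), and `other_change` (label changes entirely outside the wetland
#' classes). Guard-year labels observed after the analysis span may overturn
#' a provisional permanent call into a fluctuation.
#'
#' @param labels Integer legend codes, one per analysis year (no gaps).
#' @param guard_labels Optional labels for years after the span.
#' @param wetland Codes counted as tidal wetland (marsh, mangrove, flat).
#' @return List: `class` (stratum name), `first_change` (index of the first
#'   change year, `NA` if none), `recovery` (index at which wetland status
#'   returned, `NA` otherwise).
#' @export
classify_trajectory <- function(labels, guard_labels = integer(0),
                                wetland = wetland_extent_classes()) {
  if (any(is.na(labels))) stopf("trajectory has missing years")
  n <- length(labels)
  all_lab <- c(labels, guard_labels)
  w <- all_lab %in% wetland
  n_all <- length(all_lab)
  changes <- which(labels[-1] != labels[-n]) + 1L
  first_change <- if (length(changes)) changes[1] else NA_integer_
  if (!length(changes))   # no change inside the analysis span
    return(list(class = "stable", first_change = NA_integer_, recovery = NA_integer_))
  wtrans <- which(w[-1] != w[-n_all]) + 1L       # wetland-status transitions
  if (!length(wtrans)) {
    # status never changed; any label changes are internal
    cls <- if (w[1]) "fluctuation" else "other_change"
    return(list(class = cls, first_change = first_change, recovery = NA_integer_))
  }
  start_w <- w[1]; end_w <- w[n_all]
  if (start_w && !end_w) {
    return(list(class = "permanent_loss",
                first_change = min(wtrans[wtrans <= n] , n),
                recovery = NA_integer_))
  }
  if (!start_w && end_w) {
    return(list(class = "permanent_gain",
                first_change = min(wtrans[wtrans <= n], n),
                recovery = NA_integer_))
  }
  # status returned to where it started: temporary change
  rec <- wtrans[length(wtrans)]
  list(class = "fluctuation", first_change = wtrans[1],
       recovery = if (rec <= n) rec else NA_integer_)
}

#' Trajectory stratum map for a scene
#'
#' @param maps Integer matrix `n_years x n_pixels` of annual labels.
#' @param guard Optional matrix of guard-year labels (`n_guard x n_pixels`).
#' @return Character vector of stratum names per pixel.
#' @export
trajectory_strata <- function(maps, guard = NULL) {
  vapply(seq_len(ncol(maps)), function(p) {
    g <- if (is.null(guard)) integer(0) else guard[, p]
    classify_trajectory(maps[, p], g)$class
  }, character(1))
}

#' Mangrove dieback events in a label trajectory
#'
#' A dieback event is a maximal run of mangrove-dieback labels lasting at
#' least two years (more than one growing season under the annual-map
#' convention). Single-year dieback labels are reported separately as
#' sub-threshold.
#'
#' @param labels Integer legend codes per year.
#' @param years Calendar years (parallel to `labels`).
#' @return Data frame with `start_year`, `duration`, `recovered` (mangrove
#'   again after the run); attribute `sub_threshold` holds single-year run
#'   start years.
#' @export
dieback_events <- function(labels, years = seq_along(labels)) {
  code <- wetland_classes()[["mangrove_dieback"]]
  r <- rle(labels == code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  die <- which(r$values)
  keep <- die[r$lengths[die] >= 2]
  subthr <- die[r$lengths[die] == 1]
  recovered <- vapply(keep, function(i) {
    after <- ends[i] + 1L
    after <= length(labels) && labels[after] == wetland_classes()[["mangrove"]]
  }, logical(1))
  out <- data.frame(start_year = years[starts[keep]],
                    duration = r$lengths[keep],
                    recovered = recovered)
  attr(out, "sub_threshold") <- years[starts[subthr]]
  out
}
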