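#' Composite observations to a 32-day cadence
#'
#' Standardizes a clear-observation stream to the analysis cadence: within
#' each 32-day window (anchored at January 1 of each year) the retained
#' observation is the one maximizing the NIR-to-blue ratio; if a year still
#' holds more than `yearly_cap` composites, exactly `yearly_cap` are kept by
#' seeded uniform sampling. Non-clear observations are dropped first.
#' Compositing never invents values: every output row is an input row.
#'
#' @param series Observation data frame (`time`, band columns, `qa`, `tide`).
#' @param window_days Compositing window length (days).
#' @param yearly_cap Maximum observations retained per calendar year.
#' @param seed Seed for the yearly-cap subsampling.
#' @return The composited series, time-ordered, with attribute `prep_log`
#'   (counts dropped per rule).
#' @export
composite_32day <- function(series, window_days = 32, yearly_cap = 12, seed = 1L) {
  n0 <- nrow(series)
  s <- series[series$qa, , drop = FALSE]
  n_clear <- nrow(s)
  if (!n_clear) {
    attr(s, "prep_log") <- c(input = n0, not_clear = n0 - n_clear,
                             window_dropped = 0L, cap_dropped = 0L)
    return(s)
  }
  s <- s[order(s$time), , drop = FALSE]
  yr <- floor(s$time)
  doy <- (s$time - yr) * 365.25
  win <- paste(yr, floor(doy / window_days), sep = ":")
  blue <- pmax(s$blue, 1e-4)   # floor non-positive blue before the ratio
  ratio <- s$nir / blue
  keep <- unlist(lapply(split(seq_len(nrow(s)), win),
                        function(idx) idx[which.max(ratio[idx])]),
                 use.names = FALSE)
  keep <- sort(keep)
  n_win <- length(keep)
  s <- s[keep, , drop = FALSE]
  yr <- yr[keep]
  keep2 <- withr::with_seed(seed, unlist(lapply(split(seq_len(nrow(s)), yr),
    function(idx) {
      if (length(idx) <= yearly_cap) idx else sort(sample(idx, yearly_cap))
    }), use.names = FALSE))
  keep2 <- sort(keep2)
  out <- s[keep2, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pixel") <- attr(series, "pixel")
  attr(out, "prep_log") <- c(input = n0, not_clear = n0 - n_clear,
                             window_dropped = n_clear - n_win,
                             cap_dropped = n_win - length(keep2))
  out
}

#' Attach tide heights from the nearest valid pixel
#'
#' Each pixel's observations carry the water-level height of that pixel when
#' the water-level model covers it; pixels outside coverage inherit the
#' heights of the nearest covered pixel (Euclidean distance on the grid,
#' ties broken by row-major order). Idempotent: a fully valid input is
#' returned unchanged.
#'
#' @param tide Matrix of heights, `n_times x n_pixels` (pixels row-major),
#'   with `NA` columns where the model has no coverage.
#' @param nrow,ncol Grid dimensions.
#' @return List with `tide` (filled matrix) and `source` (for each pixel, the
#'   pixel index its heights came from).
#' @export
attach_tide <- function(tide, nrow, ncol) {
  npx <- nrow * ncol
  stopifnot(ncol(tide) == npx)
  valid <- !apply(tide, 2, anyNA)
  if (!any(valid)) stopf("no pixel has valid water-level predictions")
  source <- seq_len(npx)
  if (any(!valid)) {
    vidx <- which(valid)
    vrc <- px_rowcol(vidx, ncol)
    for (p in which(!valid)) {
      rc <- px_rowcol(p, ncol)
      d2 <- (vrc[, "row"] - rc[1, "row"])^2 + (vrc[, "col"] - rc[1, "col"])^2
      # ties: vidx is ascending row-major, which.min takes the first
      src <- vidx[which.min(d2)]
      tide[, p] <- tide[, src]
      source[p] <- src
    }
  }
  list(tide = tide, source = source)
}

#' Prepare every pixel of a scene
#'
#' Applies [attach_tide()] to the scene's water-level stack and
#' [composite_32day()] to every pixel's series.
#'
#' @param scene A `wet_scene`.
#' @param yearly_cap Maximum observations per year.
#' @param seed Seed for cap subsampling.
#' @return List of prepped per-pixel data frames (row-major pixel order).
#' @export
prep_scene <- function(scene, yearly_cap = 12, seed = 1L) {
  filled <- attach_tide(scene$tide, scene$nrow, scene$ncol)
  bn <- band_names()
  npx <- scene$nrow * scene$ncol
  lapply(seq_len(npx), function(p) {
    out <- data.frame(time = scene$times)
    for (j in seq_along(bn)) out[[bn[j]]] <- scene$refl[, j, p]
    out$qa <- scene$clear[, p]
    out$tide <- filled$tide[, p]
    composite_32day(out, yearly_cap = yearly_cap, seed = seed + p)
  })
}
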