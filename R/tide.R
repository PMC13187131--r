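#' Harmonic water-level model
#'
#' A deterministic water-level surrogate built from a mean level plus a sum
#' of harmonic constituents. Besides astronomical tidal constituents (e.g.
#' the semidiurnal M2/S2 pair, which alias to irregular scatter at a 32-day
#' observation cadence), constituents with multi-year periods can represent
#' low-frequency sea-level variability; both confound optical reflectance of
#' intertidal surfaces.
#'
#' @param mean_level Mean water level (m, scene vertical datum).
#' @param constituents Data frame (or NULL) with columns `amplitude` (m, >= 0),
#'   `period` (days, > 0) and `phase` (radians).
#' @return An object of class `tide_model`.
#' @export
#' @examples
#' tm <- tide_model(0.3, data.frame(amplitude = 0.5, period = 0.5175, phase = 0))
#' tide_heights(tm, c(2000, 2000.1))
tide_model <- function(mean_level = 0, constituents = NULL) {
  if (is.null(constituents)) {
    constituents <- data.frame(amplitude = numeric(0), period = numeric(0),
                               phase = numeric(0))
  }
  constituents <- as.data.frame(constituents)
  need <- c("amplitude", "period", "phase")
  if (!all(need %in% names(constituents)))
    stopf("constituents must have columns %s", paste(need, collapse = ", "))
  if (any(constituents$amplitude < 0)) stopf("constituent amplitudes must be >= 0")
  if (any(constituents$period <= 0)) stopf("constituent periods must be > 0")
  structure(list(mean_level = mean_level, constituents = constituents),
            class = "tide_model")
}

#' Evaluate a water-level model
#'
#' height(t) = mean_level + sum_k A_k * cos(2*pi*t / T_k - phi_k), with t in
#' decimal years and constituent periods given in days.
#'
#' @param model A [tide_model()].
#' @param times Decimal years (finite).
#' @return Numeric vector of heights (m), same length as `times`.
#' @export
tide_heights <- function(model, times) {
  stopifnot(inherits(model, "tide_model"))
  if (any(!is.finite(times))) stopf("times must be finite")
  h <- rep(model$mean_level, length(times))
  cs <- model$constituents
  if (nrow(cs)) {
    period_yr <- cs$period / 365.25
    for (k in seq_len(nrow(cs))) {
      h <- h + cs$amplitude[k] * cos(2 * pi * times / period_yr[k] - cs$phase[k])
    }
  }
  h
}
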