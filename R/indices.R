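#' Wetland-related spectral indices
#'
#' Appends the five index columns (NDVI, NDWI, mNDWI, EVI, LSWI) to an
#' observation data frame. Normalized-difference denominators are floored at
#' `1e-6` in magnitude so degenerate band values cannot divide by zero.
#'
#' @param series Data frame with the reflectance band columns.
#' @return `series` with columns `ndvi`, `ndwi`, `mndwi`, `evi`, `lswi`.
#' @export
#' @examples
#' compute_indices(data.frame(blue = .05, green = .07, red = .06,
#'                            nir = .35, swir1 = .22, swir2 = .12))
compute_indices <- function(series) {
  nd <- function(a, b) (a - b) / pmax(abs(a + b), 1e-6) * sign_or_one(a + b)
  series$ndvi <- nd(series$nir, series$red)
  series$ndwi <- nd(series$green, series$nir)
  series$mndwi <- nd(series$green, series$swir1)
  den <- series$nir + 6 * series$red - 7.5 * series$blue + 1
  series$evi <- 2.5 * (series$nir - series$red) / pmax(abs(den), 1e-6) * sign_or_one(den)
  series$lswi <- nd(series$nir, series$swir1)
  series
}

sign_or_one <- function(x) ifelse(x < 0, -1, 1)
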