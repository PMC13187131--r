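#' Class legend and band conventions
#'
#' The map legend has six classes. "Other coastal land cover" is trained as
#' subclasses (upland vegetation, developed/barren) and merged on output.
#' Integer codes are fixed so that rasters written by different stages agree:
#' 1 tidal marsh, 2 mangrove, 3 tidal flat, 4 mangrove dieback, 5 open water,
#' 6 other, 0 nodata.
#'
#' @return Named integer vector mapping class name to raster code.
#' @export
#' @examples
#' wetland_classes()
wetland_classes <- function() {
  c(tidal_marsh = 1L, mangrove = 2L, tidal_flat = 3L, mangrove_dieback = 4L,
    open_water = 5L, other = 6L)
}

# training-time subclasses of "other"; merged to code 6 on output
other_subclasses <- function() {
  c(upland_vegetation = 61L, developed_barren = 62L)
}

#' @rdname wetland_classes
#' @export
wetland_class_names <- function() names(wetland_classes())

#' Classes counted as tidal wetland extent
#'
#' Tidal wetland extent comprises tidal marsh, mangrove and tidal flat.
#' Mangrove dieback is a distinct condition class tracked separately and is
#' not counted in wetland extent, so a mangrove-to-dieback conversion is a
#' wetland loss until the canopy recovers.
#'
#' @return Integer class codes.
#' @export
wetland_extent_classes <- function() {
  unname(wetland_classes()[c("tidal_marsh", "mangrove", "tidal_flat")])
}

#' Spectral band names
#'
#' Six surface-reflectance bands plus thermal brightness (scaled to a 0-1
#' range like reflectance so one noise model covers all seven).
#'
#' @param reflective If `TRUE`, only the six reflectance bands.
#' @return Character vector of band names.
#' @export
band_names <- function(reflective = FALSE) {
  b <- c("blue", "green", "red", "nir", "swir1", "swir2", "thermal")
  if (reflective) b[1:6] else b
}

#' Wetland-related spectral indices
#'
#' The five indices used alongside the seven bands for segment
#' classification: NDVI, NDWI, mNDWI, EVI and LSWI. The set is configurable
#' at the feature-extraction call sites; these are the defaults.
#'
#' @return Character vector of index names.
#' @export
index_names <- function() c("ndvi", "ndwi", "mndwi", "evi", "lswi")

# default area of one pixel, m^2 (30 m x 30 m)
PIXEL_AREA_M2 <- 900
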