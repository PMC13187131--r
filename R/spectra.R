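#' Default class spectral specifications
#'
#' Per-class mean reflectance, annual cosine/sine seasonal amplitudes and
#' noise standard deviation for the seven bands (six reflectance + scaled
#' thermal brightness). Values are fixed plausible constants for the cover
#' types of the legend -- vegetated marsh and mangrove with high NIR, wet
#' sediment flats, spectrally degraded dieback with elevated SWIR, dark
#' water -- not fitted to any dataset; they exist so the pipeline can be
#' exercised and validated end-to-end without external downloads.
#'
#' @param noise_scale Multiplier on every per-band noise sd (default 1).
#' @return A named list of class specs; each has `mean`, `amp_cos`, `amp_sin`
#'   and `noise_sd`, all length-7 named numeric vectors, plus `class_id`.
#'   Includes the six legend classes and the two training subclasses of
#'   "other".
#' @export
#' @examples
#' sp <- default_class_spectra()
#' sp$tidal_marsh$mean["nir"]
default_class_spectra <- function(noise_scale = 1) {
  bn <- band_names()
  mk <- function(id, mean, amp_cos, amp_sin, noise_sd) {
    stopifnot(length(mean) == 7, length(amp_cos) == 7, length(amp_sin) == 7)
    list(class_id = id,
         mean = stats::setNames(mean, bn),
         amp_cos = stats::setNames(amp_cos, bn),
         amp_sin = stats::setNames(amp_sin, bn),
         noise_sd = stats::setNames(rep(noise_sd * noise_scale, 7), bn))
  }
  list(
    tidal_marsh = mk("tidal_marsh",
      mean    = c(0.040, 0.070, 0.060, 0.350, 0.220, 0.120, 0.550),
      amp_cos = c(0.002, 0.005, 0.008, 0.060, 0.030, 0.015, 0.060),
      amp_sin = c(0.001, 0.003, 0.004, 0.030, 0.015, 0.008, 0.030),
      noise_sd = 0.012),
    mangrove = mk("mangrove",
      mean    = c(0.030, 0.050, 0.040, 0.430, 0.150, 0.070, 0.500),
      amp_cos = c(0.001, 0.002, 0.002, 0.020, 0.008, 0.004, 0.040),
      amp_sin = c(0.001, 0.001, 0.001, 0.010, 0.004, 0.002, 0.020),
      noise_sd = 0.012),
    tidal_flat = mk("tidal_flat",
      mean    = c(0.085, 0.105, 0.115, 0.145, 0.130, 0.100, 0.600),
      amp_cos = c(0.003, 0.004, 0.005, 0.008, 0.006, 0.005, 0.050),
      amp_sin = c(0.002, 0.002, 0.003, 0.004, 0.003, 0.002, 0.025),
      noise_sd = 0.014),
    mangrove_dieback = mk("mangrove_dieback",
      mean    = c(0.060, 0.090, 0.110, 0.200, 0.270, 0.200, 0.630),
      amp_cos = c(0.002, 0.003, 0.004, 0.010, 0.010, 0.008, 0.050),
      amp_sin = c(0.001, 0.002, 0.002, 0.005, 0.005, 0.004, 0.025),
      noise_sd = 0.014),
    open_water = mk("open_water",
      mean    = c(0.050, 0.058, 0.040, 0.022, 0.012, 0.008, 0.500),
      amp_cos = c(0.002, 0.002, 0.002, 0.002, 0.001, 0.001, 0.045),
      amp_sin = c(0.001, 0.001, 0.001, 0.001, 0.001, 0.001, 0.020),
      noise_sd = 0.010),
    upland_vegetation = mk("upland_vegetation",
      mean    = c(0.038, 0.078, 0.068, 0.300, 0.290, 0.170, 0.580),
      amp_cos = c(0.004, 0.010, 0.015, 0.090, 0.040, 0.025, 0.070),
      amp_sin = c(0.002, 0.005, 0.008, 0.045, 0.020, 0.012, 0.035),
      noise_sd = 0.014),
    developed_barren = mk("developed_barren",
      mean    = c(0.120, 0.140, 0.160, 0.200, 0.240, 0.220, 0.660),
      amp_cos = c(0.002, 0.002, 0.003, 0.004, 0.004, 0.004, 0.060),
      amp_sin = c(0.001, 0.001, 0.002, 0.002, 0.002, 0.002, 0.030),
      noise_sd = 0.014)
  )
}

# seasonal spectrum of a class at decimal-year times: matrix [n_times x 7]
class_seasonal <- function(spec, times) {
  w <- 2 * pi * times
  outer(rep(1, length(times)), spec$mean) +
    outer(cos(w), spec$amp_cos) + outer(sin(w), spec$amp_sin)
}

# spectra list entry for a class code (subclass codes included)
spec_for_code <- function(spectra, code) {
  nm <- c(names(wetland_classes()), names(other_subclasses()))
  cd <- c(unname(wetland_classes()), unname(other_subclasses()))
  name <- nm[match(code, cd)]
  if (is.na(name)) stopf("unknown class code %s", code)
  if (name == "other") name <- "upland_vegetation"
  spectra[[name]]
}
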