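#' Convert CT Hounsfield units to 511 keV linear attenuation
#'
#' Bilinear CT-based attenuation conversion for PET attenuation
#' correction: below the soft-tissue/bone breakpoint the attenuation
#' scales with the water-like slope, above it with the shallower
#' bone-mixture slope; the upper branch is anchored at the breakpoint so
#' the transform is continuous by construction.
#'
#' With the defaults:
#' \deqn{\mu = 9.6\times10^{-5} (HU + 1000)\ \mathrm{cm}^{-1},\quad HU \le 47}
#' \deqn{\mu = \mu(47) + 5.1\times10^{-5} (HU - 47)\ \mathrm{cm}^{-1},\quad HU > 47}
#'
#' @param hu Hounsfield units, numeric vector; must be >= -1000 (air).
#' @param breakpoint branch point in HU (default 47).
#' @param slope_low slope below the breakpoint, cm^-1 per HU.
#' @param slope_high slope above the breakpoint, cm^-1 per HU.
#' @return linear attenuation coefficient(s) at 511 keV in cm^-1.
#' @export
hu_to_mu511 <- function(hu, breakpoint = 47,
                        slope_low = 9.6e-5, slope_high = 5.1e-5) {
  if (any(!is.finite(hu)) || any(hu < -1000))
    stop("'hu' must be finite and >= -1000")
  mu_bp <- slope_low * (breakpoint + 1000)
  ifelse(hu <= breakpoint,
         slope_low * (hu + 1000),
         mu_bp + slope_high * (hu - breakpoint))
}
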