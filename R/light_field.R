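#' Beer-Lambert transmittance of seawater
#'
#' Fraction of downwelling irradiance surviving to a given depth,
#' `exp(-k * depth)`. The default absorption coefficient is that of
#' non-turbid ocean water at 550 nm, 0.0562 per metre.
#'
#' @param depth depth in metres, non-negative (vectorized).
#' @param k absorption coefficient per metre, non-negative.
#' @return transmittance fraction(s) in `(0, 1]`.
#' @export
transmittance <- function(depth, k = 0.0562) {
  stopifnot(k >= 0)
  if (any(depth < 0)) stop("depth must be non-negative")
  exp(-k * depth)
}

#' Irradiance at depth from surface irradiance and transmittance
#'
#' The transmittance is an explicit argument (rather than recomputed from
#' a depth) so that independently reported transmittance percentages can
#' be combined with a surface value directly. The default surface value
#' is a starlight irradiance of 0.0002 lux, i.e. 1.46e-10 W/cm^2.
#'
#' @param T_frac transmittance fraction(s) in `[0, 1]`.
#' @param surface surface irradiance in W/cm^2.
#' @return irradiance in W/cm^2.
#' @export
irradiance_at_depth <- function(T_frac, surface = 1.46e-10) {
  stopifnot(surface >= 0)
  if (any(T_frac < 0 | T_frac > 1))
    stop("transmittance must lie in [0, 1]")
  surface * T_frac
}

#' Starlight attenuation table
#'
#' Convenience wrapper computing Beer-Lambert transmittance and the
#' resulting irradiance for a set of depths.
#'
#' @param depths depths in metres.
#' @param k absorption coefficient per metre.
#' @param surface surface irradiance in W/cm^2.
#' @return `data.frame` with columns `depth_m`, `transmittance`,
#'   `irradiance_w_cm2`.
#' @export
starlight_at_depth <- function(depths, k = 0.0562, surface = 1.46e-10) {
  tr <- transmittance(depths, k)
  data.frame(depth_m = depths, transmittance = tr,
             irradiance_w_cm2 = irradiance_at_depth(tr, surface))
}
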