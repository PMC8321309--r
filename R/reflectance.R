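#' Top-of-atmosphere reflectance from at-sensor radiance
#'
#' Converts spectral radiance at the sensor's aperture to the dimensionless
#' top-of-atmosphere (TOA) reflectance
#' \deqn{q_p = \frac{\pi \, L_\lambda \, d^2}{ESUN_\lambda \cos\theta_s}}
#' where \eqn{L_\lambda} is at-sensor radiance
#' (W m\eqn{^{-2}} sr\eqn{^{-1}} \eqn{\mu}m\eqn{^{-1}}), \eqn{d} the
#' Earth-Sun distance in astronomical units, \eqn{ESUN_\lambda} the mean
#' solar exo-atmospheric irradiance (W m\eqn{^{-2}} \eqn{\mu}m\eqn{^{-1}})
#' and \eqn{\theta_s} the solar zenith angle. The zenith angle is derived
#' from the sun elevation as \eqn{\theta_s = 90 - \theta_e} when only the
#' elevation is given. Valid conversion requires \eqn{0 \le \theta_s < 90}.
#'
#' @param radiance at-sensor spectral radiance \eqn{L_\lambda}; scalar,
#'   vector or matrix.
#' @param d Earth-Sun distance in astronomical units (> 0).
#' @param esun mean solar exo-atmospheric irradiance (> 0).
#' @param sun_elevation sun elevation \eqn{\theta_e} in degrees; used when
#'   `solar_zenith` is missing.
#' @param solar_zenith solar zenith \eqn{\theta_s} in degrees.
#' @return Reflectance with the shape of `radiance`; linear in `radiance`.
#' @examples
#' toa_reflectance(100, d = 1, esun = 1000, solar_zenith = 0) # ~0.31416
#' @export
toa_reflectance <- function(radiance, d, esun, sun_elevation = NULL,
                            solar_zenith = NULL) {
  if (is.null(solar_zenith)) {
    if (is.null(sun_elevation))
      stop("either 'sun_elevation' or 'solar_zenith' is required")
    solar_zenith <- 90 - sun_elevation
  }
  if (!is.numeric(d) || d <= 0) stop("'d' must be > 0")
  if (!is.numeric(esun) || esun <= 0) stop("'esun' must be > 0")
  if (solar_zenith < 0 || solar_zenith >= 90)
    stop("solar zenith angle must lie in [0, 90): sun at or below horizon")
  pi * radiance * d^2 / (esun * cos(solar_zenith * pi / 180))
}

#' Convert a digital-number scene to TOA reflectance
#'
#' Each band's digital numbers are first mapped to radiance by a per-band
#' linear rescale `radiance = gain * DN + offset` (use `gain = 1`,
#' `offset = 0` if the scene already stores radiance), then converted with
#' [toa_reflectance()] using the scene-level Earth-Sun distance and sun
#' elevation. Nodata pixels pass through unchanged.
#'
#' @param scene a [multiband_scene()].
#' @param params list with scalars `d` and `sun_elevation` (or
#'   `solar_zenith`) and a named list `bands` mapping each band id of the
#'   scene to `list(gain =, offset =, esun =)`; see [read_toa_config()].
#' @return A [multiband_scene()] with `units = "reflectance"`.
#' @export
apply_toa <- function(scene, params) {
  stopifnot(inherits(scene, "mb_scene"))
  if (is.null(params$bands)) stop("TOA configuration lacks a 'bands' block")
  missing_b <- setdiff(scene$band_ids, names(params$bands))
  if (length(missing_b))
    stop(sprintf("missing TOA parameters for band(s): %s",
                 paste(missing_b, collapse = ", ")))
  out <- lapply(scene$band_ids, function(id) {
    bp <- params$bands[[id]]
    if (is.null(bp$esun)) stop(sprintf("band '%s': 'esun' missing", id))
    gain <- if (is.null(bp$gain)) 1 else bp$gain
    offset <- if (is.null(bp$offset)) 0 else bp$offset
    b <- scene$bands[[id]]
    nd <- !is.null(scene$nodata) & b == if (is.null(scene$nodata)) Inf else scene$nodata
    q <- toa_reflectance(gain * b + offset, d = params$d, esun = bp$esun,
                         sun_elevation = params$sun_elevation,
                         solar_zenith = params$solar_zenith)
    q[nd] <- b[nd]
    q
  })
  multiband_scene(out, band_ids = scene$band_ids, nodata = scene$nodata,
                  pixel_size = scene$pixel_size, units = "reflectance",
                  geo = scene$geo)
}

#' Read a TOA conversion configuration
#'
#' YAML or JSON (by file extension) with scene-level `d` and
#' `sun_elevation` and a `bands` block of per-band `gain`, `offset`,
#' `esun`.
#'
#' @param path configuration file path.
#' @return A list suitable for [apply_toa()].
#' @export
read_toa_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::fromJSON(path)
  else stop("TOA config must be YAML or JSON")
}
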