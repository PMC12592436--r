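# Solar geometry. Declination, equation of time and the Sun-Earth distance
# factor follow the classical Fourier expansions in day-of-year (Spencer);
# zenith angles agree with astronomical almanac values to within ~0.3
# degrees, sufficient for monthly-mean irradiance work.

.day_angle <- function(doy) 2 * pi * (doy - 1) / 365

.declination <- function(doy) {
  g <- .day_angle(doy)
  0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)   # radians
}

.eqtime_min <- function(doy) {
  g <- .day_angle(doy)
  229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
              0.014615 * cos(2 * g) - 0.04089 * sin(2 * g))
}

.distance_factor <- function(doy) {
  g <- .day_angle(doy)
  1.00011 + 0.034221 * cos(g) + 0.00128 * sin(g) +
    0.000719 * cos(2 * g) + 0.000077 * sin(2 * g)
}

# zenith (degrees) from latitude, declination (rad) and hour angle (deg)
.zenith_deg <- function(lat_deg, decl_rad, hour_angle_deg) {
  phi <- lat_deg * pi / 180
  h <- hour_angle_deg * pi / 180
  mu <- sin(phi) * sin(decl_rad) + cos(phi) * cos(decl_rad) * cos(h)
  acos(pmin(pmax(mu, -1), 1)) * 180 / pi
}

#' Solar position for a place and UTC time
#'
#' @param lat,lon coordinates in degrees (north/east positive).
#' @param timestamp a `POSIXct` time (interpreted in UTC).
#' @return An object of class `solar_geometry`: list with `lat`, `lon`,
#'   `timestamp`, `zenith` (degrees, 0 = overhead), and `distance_factor`
#'   (dimensionless irradiance multiplier for the Sun--Earth distance).
#' @export
#' @examples
#' g <- solar_position(60, 0, as.POSIXct("2000-06-21 12:00", tz = "UTC"))
#' round(g$zenith, 1)
solar_position <- function(lat, lon, timestamp) {
  stopifnot(abs(lat) <= 90)
  tt <- as.POSIXlt(timestamp, tz = "UTC")
  doy <- tt$yday + 1
  hours <- tt$hour + tt$min / 60 + tt$sec / 3600
  lst <- hours + lon / 15 + .eqtime_min(doy) / 60   # local solar time
  ha <- 15 * (lst - 12)
  z <- .zenith_deg(lat, .declination(doy), ha)
  structure(list(lat = lat, lon = lon, timestamp = timestamp,
                 zenith = z, distance_factor = .distance_factor(doy)),
            class = "solar_geometry")
}

#' Construct a solar geometry directly from zenith angle
#'
#' Convenience constructor used when the zenith angle is prescribed (tests,
#' idealized experiments) rather than derived from a time and place.
#'
#' @param zenith solar zenith angle, degrees.
#' @param distance_factor Sun--Earth distance irradiance factor.
#' @return A `solar_geometry`.
#' @export
solar_geometry <- function(zenith, distance_factor = 1) {
  stopifnot(zenith >= 0, zenith <= 180,
            distance_factor >= 0.96, distance_factor <= 1.04)
  structure(list(lat = NA_real_, lon = NA_real_, timestamp = NA,
                 zenith = zenith, distance_factor = distance_factor),
            class = "solar_geometry")
}

# relative (pressure-uncorrected) air mass, Kasten & Young style
.airmass <- function(zenith_deg) {
  z <- pmin(zenith_deg, 89.999)
  1 / (cos(z * pi / 180) + 0.50572 * (96.07995 - z)^-1.6364)
}

# ozone air mass with a 22 km effective layer height
.airmass_ozone <- function(zenith_deg) {
  mu <- cos(pmin(zenith_deg, 89.999) * pi / 180)
  1.0035 / sqrt(mu^2 + 0.007)
}
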