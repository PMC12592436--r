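#' Regular 1-degree analysis grid
#'
#' The fixed Cartesian longitude-latitude grid on which all fields are
#' evaluated: cell centers at integer latitudes 60..85 degrees N and integer
#' longitudes 0..359 degrees E.
#'
#' @param lat_range integer vector of length 2, inclusive latitude span.
#' @return An object of class `cryo_grid` with elements `lat` and `lon`
#'   (cell-center coordinates, degrees).
#' @export
#' @examples
#' g <- grid_1x1()
#' length(g$lat) # 26
grid_1x1 <- function(lat_range = c(60L, 85L)) {
  stopifnot(length(lat_range) == 2, lat_range[1] < lat_range[2],
            lat_range[1] >= -90, lat_range[2] <= 90)
  structure(list(lat = seq(lat_range[1], lat_range[2], by = 1),
                 lon = seq(0, 359, by = 1)),
            class = "cryo_grid")
}

#' @export
print.cryo_grid <- function(x, ...) {
  cat(sprintf("<cryo_grid> %d lat x %d lon, lat %g..%g, lon %g..%g\n",
              length(x$lat), length(x$lon),
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  invisible(x)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$lat, b$lat)) && isTRUE(all.equal(a$lon, b$lon))
}

#' Area of a longitude-latitude grid cell
#'
#' Spherical cell area `dA = R^2 dphi dlambda cos(phi)` with R = 6371 km and
#' the angular spacings converted to radians.
#'
#' @param phi latitude of the cell center, degrees.
#' @param dphi,dlam latitudinal and longitudinal cell widths, degrees.
#' @param radius_km Earth radius, km.
#' @return Cell area in km^2 (vectorized over `phi`).
#' @export
#' @examples
#' cell_area(60) / cell_area(0) # 0.5
cell_area <- function(phi, dphi = 1, dlam = 1, radius_km = 6371) {
  stopifnot(all(abs(phi) <= 90))
  deg <- pi / 180
  pmax(radius_km^2 * (dphi * deg) * (dlam * deg) * cos(phi * deg), 0)
}
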