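# Forcing fields: one variable on a rectilinear lon/lat grid with monthly
# timestamps. Values are stored as an array [time, lat, lon]. Internal unit
# conventions: fractions in [0,1] (siconc, sisnconc, clt), temperatures in
# degC (tas, tos), thicknesses in m, chl in mg m-3, toz in DU, prw in
# kg m-2, winds in m s-1.

FORCING_VARS <- c("tas", "siconc", "sisnthick", "chl", "sithick", "sisnconc",
                  "clt", "uas", "vas", "toz", "tos", "prw")

# canonical internal units and admissible range per variable
.var_info <- function(variable_id) {
  info <- list(
    tas       = list(units = "degC",    lo = -90,  hi = 60),
    tos       = list(units = "degC",    lo = -2.5, hi = 45),
    siconc    = list(units = "1",       lo = 0,    hi = 1),
    sisnconc  = list(units = "1",       lo = 0,    hi = 1),
    clt       = list(units = "1",       lo = 0,    hi = 1),
    sisnthick = list(units = "m",       lo = 0,    hi = Inf),
    sithick   = list(units = "m",       lo = 0,    hi = Inf),
    chl       = list(units = "mg m-3",  lo = 0,    hi = Inf),
    toz       = list(units = "DU",      lo = 1e-6, hi = Inf),
    prw       = list(units = "kg m-2",  lo = 0,    hi = Inf),
    uas       = list(units = "m s-1",   lo = -150, hi = 150),
    vas       = list(units = "m s-1",   lo = -150, hi = 150))
  if (!variable_id %in% names(info))
    stop("unknown variable_id: ", variable_id)
  info[[variable_id]]
}

#' Construct a forcing field
#'
#' @param variable_id one of the twelve forcing variable names
#'   (`tas, siconc, sisnthick, chl, sithick, sisnconc, clt, uas, vas, toz,
#'   tos, prw`).
#' @param values numeric array with dimensions `[time, lat, lon]`. `NA`
#'   marks missing cells; missing cells are skipped downstream, never
#'   treated as zero.
#' @param lat,lon strictly increasing cell-center coordinates (degrees).
#' @param time vector of `Date` monthly timestamps (one per month, placed
#'   on the 15th).
#' @param units units of `values` as supplied; converted to the internal
#'   convention (`K` to `degC` for tas/tos, `%` to fraction for
#'   siconc/sisnconc/clt).
#' @param scenario,model_id,realization_id provenance tags.
#' @param check validate invariants (bounds, monotone monthly time)?
#' @return An object of class `forcing_field`.
#' @export
forcing_field <- function(variable_id, values, lat, lon, time,
                          units = NULL, scenario = "historical",
                          model_id = "unknown", realization_id = "r1",
                          check = TRUE) {
  variable_id <- match.arg(variable_id, FORCING_VARS)
  info <- .var_info(variable_id)
  if (is.null(units)) units <- info$units
  values <- .normalize_units(variable_id, values, units)
  if (!is.array(values) || length(dim(values)) != 3)
    stop("values must be a [time, lat, lon] array")
  if (dim(values)[1] != length(time) || dim(values)[2] != length(lat) ||
      dim(values)[3] != length(lon))
    stop("values dimensions do not match time/lat/lon lengths")
  x <- structure(list(variable_id = variable_id, values = values,
                      lat = as.numeric(lat), lon = as.numeric(lon),
                      time = as.Date(time), units = info$units,
                      scenario = scenario, model_id = model_id,
                      realization_id = realization_id),
                 class = "forcing_field")
  if (check) validate_forcing(x)
  x
}

.normalize_units <- function(variable_id, values, units) {
  if (variable_id %in% c("tas", "tos") && units %in% c("K", "kelvin"))
    return(values - 273.15)
  if (variable_id %in% c("siconc", "sisnconc", "clt") &&
      units %in% c("%", "percent"))
    return(values / 100)
  values
}

#' Validate forcing-field invariants
#'
#' Checks bounds per variable (fractions in \[0,1\], thicknesses and chl
#' nonnegative, toz positive) and a strictly increasing monthly time axis.
#' Missing cells (`NA`) are permitted.
#'
#' @param x a `forcing_field`.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_forcing <- function(x) {
  stopifnot(inherits(x, "forcing_field"))
  info <- .var_info(x$variable_id)
  v <- x$values[!is.na(x$values)]
  if (length(v) && (min(v) < info$lo - 1e-9 || max(v) > info$hi + 1e-9))
    stop(sprintf("%s values outside [%g, %g]", x$variable_id, info$lo, info$hi))
  if (any(diff(x$lat) <= 0) || any(diff(x$lon) <= 0))
    stop("lat/lon must be strictly increasing")
  if (length(x$time) > 1) {
    dd <- diff(as.numeric(x$time))
    if (any(dd <= 0)) stop("time must be strictly increasing")
    if (any(dd < 28 | dd > 31.5)) stop("time must be monthly")
  }
  invisible(x)
}

#' @export
print.forcing_field <- function(x, ...) {
  cat(sprintf("<forcing_field> %s [%s] %s/%s/%s: %d months x %d lat x %d lon\n",
              x$variable_id, x$units, x$scenario, x$model_id,
              x$realization_id, length(x$time), length(x$lat), length(x$lon)))
  cat(sprintf("  %s .. %s; %d missing cells\n", format(min(x$time)),
              format(max(x$time)), sum(is.na(x$values))))
  invisible(x)
}

# ---- text serialization --------------------------------------------------
# Self-describing plain-text format for gridded monthly fields: a key:value
# header (variable_id, units, provenance, coordinate vectors) followed by
# one whitespace-separated row of nlon values per (time, lat) slice. Values
# are written with 17 significant digits so doubles round-trip exactly.

# generic writer: meta is a list with variable_id, units, scenario,
# model_id, realization_id, lat, lon, time, values
.grid_txt_write <- function(meta, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  num <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  writeLines(c("#cryolight-forcing 1",
               paste0("variable_id: ", meta$variable_id),
               paste0("units: ", meta$units),
               paste0("scenario: ", meta$scenario),
               paste0("model_id: ", meta$model_id),
               paste0("realization_id: ", meta$realization_id),
               paste0("lat: ", num(meta$lat)),
               paste0("lon: ", num(meta$lon)),
               paste0("time: ", paste(format(meta$time), collapse = " ")),
               "data:"), con)
  nt <- length(meta$time); nlat <- length(meta$lat)
  for (it in seq_len(nt))
    for (ilat in seq_len(nlat))
      writeLines(num(meta$values[it, ilat, ]), con)
  invisible(path)
}

.grid_txt_read <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#cryolight-forcing"))
    stop("not a cryolight gridded file: ", path)
  hdr_end <- match("data:", lines)
  if (is.na(hdr_end)) stop("format error: missing data section")
  hdr <- lines[2:(hdr_end - 1)]
  get <- function(key, required = TRUE) {
    i <- grep(paste0("^", key, ": "), hdr)
    if (!length(i)) {
      if (required) stop("format error: missing header field '", key, "'")
      return(NULL)
    }
    trimws(sub(paste0("^", key, ": "), "", hdr[i[1]]))
  }
  lat <- as.numeric(strsplit(get("lat"), " +")[[1]])
  lon <- as.numeric(strsplit(get("lon"), " +")[[1]])
  time <- as.Date(strsplit(get("time"), " +")[[1]])
  if (anyNA(time)) stop("format error: unparseable time coordinate")
  nt <- length(time); nlat <- length(lat); nlon <- length(lon)
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(body)]
  if (length(body) != nt * nlat) stop("format error: data row count")
  vals <- scan(text = paste(body, collapse = "\n"), quiet = TRUE,
               na.strings = c("NA", "nan"))
  if (length(vals) != nt * nlat * nlon) stop("format error: data size")
  arr <- aperm(array(vals, c(nlon, nlat, nt)), c(3, 2, 1))
  list(variable_id = get("variable_id"), units = get("units"),
       scenario = get("scenario"), model_id = get("model_id"),
       realization_id = get("realization_id"),
       lat = lat, lon = lon, time = time, values = arr)
}

#' Write a forcing field to a plain-text gridded file
#'
#' @param x a `forcing_field`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_forcing()]
#' @export
write_forcing <- function(x, path) {
  validate_forcing(x)
  .grid_txt_write(x, path)
}

#' Read a forcing field from a plain-text gridded file
#'
#' Units are normalized on read: percent fractions to \[0,1\] and kelvin
#' temperatures to degC, according to the file's `units` header.
#'
#' @param path file written by [write_forcing()] (or assembled in the same
#'   format by other tooling).
#' @param variable_id optional; if given, the file must contain this
#'   variable.
#' @return A `forcing_field`.
#' @export
read_forcing <- function(path, variable_id = NULL) {
  meta <- .grid_txt_read(path)
  if (!is.null(variable_id) && meta$variable_id != variable_id)
    stop("file contains ", meta$variable_id, ", expected ", variable_id)
  forcing_field(meta$variable_id, meta$values, meta$lat, meta$lon,
                meta$time, units = meta$units, scenario = meta$scenario,
                model_id = meta$model_id,
                realization_id = meta$realization_id)
}

# ---- regridding ----------------------------------------------------------

#' Bilinear regridding to the 1x1 analysis grid
#'
#' Interpolates a rectilinear source field to the target cell centers with
#' weighted bilinear interpolation. Longitude wraps around 0/360. Where
#' some of the four surrounding source cells are missing, the remaining
#' weights are renormalized over the valid neighbours; a target cell with
#' no valid neighbour is `NA`.
#'
#' @param field a `forcing_field` on any rectilinear grid.
#' @param target a `cryo_grid` (default [grid_1x1()]).
#' @return A `forcing_field` on `target`.
#' @export
regrid_bilinear <- function(field, target = grid_1x1()) {
  stopifnot(inherits(field, "forcing_field"))
  slat <- field$lat; slon <- field$lon
  tlat <- target$lat; tlon <- target$lon
  if (min(tlat) < min(slat) - 1e-9 || max(tlat) > max(slat) + 1e-9)
    stop("target latitudes outside source latitude span")

  # latitude bracketing (no wrap)
  i1 <- findInterval(tlat, slat, rightmost.closed = TRUE)
  i1 <- pmin(pmax(i1, 1), length(slat) - 1)
  if (length(slat) == 1) stop("source grid needs at least 2 latitudes")
  i2 <- i1 + 1
  wlat <- (tlat - slat[i1]) / (slat[i2] - slat[i1])
  wlat <- pmin(pmax(wlat, 0), 1)

  # longitude bracketing with wraparound
  nslon <- length(slon)
  lon_ext <- c(slon, slon[1] + 360)
  tlon_adj <- tlon
  tlon_adj[tlon_adj < slon[1]] <- tlon_adj[tlon_adj < slon[1]] + 360
  j1 <- findInterval(tlon_adj, lon_ext, rightmost.closed = TRUE)
  j1 <- pmin(pmax(j1, 1), nslon)
  j2 <- ifelse(j1 == nslon, 1L, j1 + 1L)
  span <- lon_ext[j1 + 1] - lon_ext[j1]
  wlon <- (tlon_adj - lon_ext[j1]) / span
  wlon <- pmin(pmax(wlon, 0), 1)

  ntlat <- length(tlat); ntlon <- length(tlon)
  ii1 <- rep(i1, times = ntlon); ii2 <- rep(i2, times = ntlon)
  jj1 <- rep(j1, each = ntlat); jj2 <- rep(j2, each = ntlat)
  wla <- rep(wlat, times = ntlon); wlo <- rep(wlon, each = ntlat)
  w <- cbind((1 - wla) * (1 - wlo), (1 - wla) * wlo,
             wla * (1 - wlo), wla * wlo)

  nt <- length(field$time)
  out <- array(NA_real_, c(nt, ntlat, ntlon))
  for (it in seq_len(nt)) {
    sl <- field$values[it, , ]
    v <- cbind(sl[cbind(ii1, jj1)], sl[cbind(ii1, jj2)],
               sl[cbind(ii2, jj1)], sl[cbind(ii2, jj2)])
    ok <- !is.na(v)
    wsum <- rowSums(w * ok)
    num <- rowSums(ifelse(ok, w * v, 0))
    res <- ifelse(wsum > 0, num / wsum, NA_real_)
    out[it, , ] <- matrix(res, ntlat, ntlon)
  }
  forcing_field(field$variable_id, out, tlat, tlon, field$time,
                units = field$units, scenario = field$scenario,
                model_id = field$model_id,
                realization_id = field$realization_id)
}

# ---- scenario splicing ---------------------------------------------------

#' Concatenate historical and scenario segments of one variable
#'
#' The two segments must describe the same variable, model, realization and
#' grid, and `future` must begin exactly one month after `historical` ends.
#'
#' @param historical,future `forcing_field`s.
#' @return A single continuous `forcing_field` tagged with the future
#'   segment's scenario.
#' @export
concat_scenarios <- function(historical, future) {
  stopifnot(inherits(historical, "forcing_field"),
            inherits(future, "forcing_field"))
  if (historical$variable_id != future$variable_id)
    stop("splice error: variable_id mismatch")
  if (historical$model_id != future$model_id ||
      historical$realization_id != future$realization_id)
    stop("splice error: model/realization mismatch")
  if (!isTRUE(all.equal(historical$lat, future$lat)) ||
      !isTRUE(all.equal(historical$lon, future$lon)))
    stop("splice error: grid mismatch")
  t_end <- historical$time[length(historical$time)]
  t_next <- seq(t_end, by = "1 month", length.out = 2)[2]
  if (future$time[1] != t_next)
    stop("splice error: future must start the month after historical ends (",
         format(t_next), " expected, got ", format(future$time[1]), ")")
  nt <- length(historical$time) + length(future$time)
  vals <- array(NA_real_, c(nt, length(historical$lat), length(historical$lon)))
  vals[seq_along(historical$time), , ] <- historical$values
  vals[length(historical$time) + seq_along(future$time), , ] <- future$values
  forcing_field(historical$variable_id, vals, historical$lat, historical$lon,
                c(historical$time, future$time), units = historical$units,
                scenario = future$scenario, model_id = historical$model_id,
                realization_id = historical$realization_id)
}

# monthly Date sequence on the 15th
month_stamps <- function(start_year, end_year) {
  as.Date(sprintf("%d-%02d-15", rep(start_year:end_year, each = 12), 1:12))
}
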