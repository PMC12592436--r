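# Regional aggregation: area-weighted means over large-marine-ecosystem
# masks, rolling means, decadal monthly anomaly tables, and
# threshold-duration metrics with fractional-month interpolation.

#' Region mask for a large marine ecosystem
#'
#' Approximate longitude/latitude boxes for the two focal ecosystems (the
#' Northern Bering--Chukchi Seas, center latitude 69.5 N, and the Barents
#' Sea, center latitude 75.0 N). User-supplied boolean masks on the same
#' grid are accepted anywhere a `region_mask` is.
#'
#' @param name `"bering_chukchi"` or `"barents"`.
#' @param grid a `cryo_grid` (or any list with `lat`, `lon`).
#' @return List of class `region_mask` with `name`, `mask`
#'   (`[lat, lon]` logical), `center_lat`, `lat`, `lon`.
#' @export
region_mask <- function(name = c("bering_chukchi", "barents"),
                        grid = grid_1x1()) {
  name <- match.arg(name)
  box <- switch(name,
                bering_chukchi = list(lat = c(64, 75), lon = c(175, 205),
                                      center = 69.5),
                barents = list(lat = c(70, 80), lon = c(20, 55),
                               center = 75.0))
  mask <- outer(grid$lat >= box$lat[1] & grid$lat <= box$lat[2],
                grid$lon >= box$lon[1] & grid$lon <= box$lon[2], `&`)
  if (!any(mask)) stop("empty region mask on this grid")
  structure(list(name = name, mask = mask, center_lat = box$center,
                 lat = grid$lat, lon = grid$lon),
            class = "region_mask")
}

.as_mask <- function(mask, lat, lon) {
  m <- if (inherits(mask, "region_mask")) mask$mask else mask
  if (!is.matrix(m) || nrow(m) != length(lat) || ncol(m) != length(lon))
    stop("mask does not match field grid")
  m
}

#' Area-weighted regional mean time series
#'
#' `sum(value * dA) / sum(dA)` over unmasked, non-missing cells, with the
#' spherical cell area [cell_area()] as weight.
#'
#' @param field list with `values` `[time, lat, lon]`, `lat`, `lon`,
#'   `time` (a `forcing_field` or [light_band()] output).
#' @param mask a [region_mask()] or logical `[lat, lon]` matrix.
#' @return Numeric vector along `field$time`.
#' @export
area_weighted_mean <- function(field, mask) {
  m <- .as_mask(mask, field$lat, field$lon)
  if (!any(m)) stop("data error: all cells masked")
  w <- matrix(cell_area(field$lat), length(field$lat), length(field$lon))
  nt <- dim(field$values)[1]
  vapply(seq_len(nt), function(it) {
    sl <- field$values[it, , ]
    ok <- m & !is.na(sl)
    if (!any(ok)) return(NA_real_)
    sum(sl[ok] * w[ok]) / sum(w[ok])
  }, numeric(1))
}

#' Centered rolling mean
#'
#' Centered window mean; at the edges the mean is taken over the window
#' points that exist (shrinking window).
#'
#' @param x numeric series.
#' @param window window length in samples (e.g. 5 for a 5-year window on
#'   an annual series).
#' @return Smoothed series, same length.
#' @export
rolling_mean <- function(x, window = 5) {
  zoo::rollapply(x, width = window, FUN = mean, na.rm = TRUE,
                 partial = TRUE, align = "center")
}

#' Decadal monthly anomaly table
#'
#' For a monthly regional series: per calendar month, the decade mean
#' minus the baseline-period mean. The first column holds the baseline
#' monthly means themselves.
#'
#' @param series numeric monthly values.
#' @param time `Date` vector matching `series`.
#' @param baseline length-2 years of the reference period (inclusive
#'   start, exclusive end + 1; default 1980--2000).
#' @param decades starting years of the decades reported.
#' @return A `data.frame`: rows = months 1..12, first column `baseline`,
#'   then one column per decade of anomalies.
#' @export
decadal_monthly_anomaly <- function(series, time,
                                    baseline = c(1980, 2000),
                                    decades = seq(2000, 2090, by = 10)) {
  yr <- as.integer(format(time, "%Y"))
  mo <- as.integer(format(time, "%m"))
  in_base <- yr >= baseline[1] & yr <= baseline[2]
  if (!any(in_base)) stop("data error: baseline period not covered")
  base_m <- vapply(1:12, function(m)
    mean(series[in_base & mo == m], na.rm = TRUE), numeric(1))
  out <- data.frame(month = 1:12, baseline = base_m)
  for (d0 in decades) {
    in_dec <- yr >= d0 & yr < d0 + 10
    col <- vapply(1:12, function(m) {
      v <- series[in_dec & mo == m]
      if (!length(v)) return(NA_real_)
      mean(v, na.rm = TRUE) - base_m[m]
    }, numeric(1))
    out[[sprintf("d%d", d0)]] <- col
  }
  out
}

#' Months per year above a threshold, with fractional interpolation
#'
#' Counts, within one half of the year, how long a monthly series exceeds
#' a threshold. The series is treated as piecewise linear between month
#' centers (flat beyond the end months), and the measure of time above
#' the threshold inside the half-year window (Jan--Jun or Jul--Dec) is
#' returned in months, so threshold crossings between month centers give
#' fractional values.
#'
#' @param series numeric monthly values.
#' @param time `Date` vector matching `series`.
#' @param threshold threshold value.
#' @param half `"winter_spring"` (Jan--Jun) or `"summer_fall"`
#'   (Jul--Dec).
#' @return `data.frame` with `year` and `months_above`; incomplete years
#'   are skipped with a warning.
#' @export
months_above_threshold <- function(series, time, threshold,
                                   half = c("winter_spring",
                                            "summer_fall")) {
  half <- match.arg(half)
  # each half-year is the 6-month interval from its first month's center
  # (January or July) to the center of the month after its last
  win <- if (half == "winter_spring") c(1, 7) else c(7, 13)
  yr <- as.integer(format(time, "%Y"))
  mo <- as.integer(format(time, "%m"))
  years <- sort(unique(yr))
  res <- lapply(years, function(y) {
    sel <- yr == y
    if (sum(sel) != 12 || anyNA(series[sel])) {
      warning("incomplete year ", y, " skipped")
      return(NULL)
    }
    v <- series[sel][order(mo[sel])]
    data.frame(year = y,
               months_above = .time_above(v, threshold, win))
  })
  do.call(rbind, res[!vapply(res, is.null, logical(1))])
}

# measure (months) of {t in [win1, win2]: v(t) > thr} for v piecewise
# linear through (m, v[m]), m = 1..12, constant outside [1, 12]
.time_above <- function(v, thr, win) {
  total <- 0
  # flat left edge
  if (win[1] < 1) total <- total + (1 - win[1]) * (v[1] > thr)
  # flat right edge
  if (win[2] > 12) total <- total + (win[2] - 12) * (v[12] > thr)
  for (m in 1:11) {
    a <- max(m, win[1]); b <- min(m + 1, win[2])
    if (b <= a) next
    v_a <- v[m] + (v[m + 1] - v[m]) * (a - m)
    v_b <- v[m] + (v[m + 1] - v[m]) * (b - m)
    if (v_a > thr && v_b > thr) {
      total <- total + (b - a)
    } else if (v_a > thr || v_b > thr) {
      # single crossing inside (a, b)
      tcross <- m + (thr - v[m]) / (v[m + 1] - v[m])
      if (v_a > thr) total <- total + (tcross - a)
      else total <- total + (b - tcross)
    }
  }
  total
}

#' Open-water fraction and area over a region
#'
#' Area fraction (and km^2) of the mask where sea-ice concentration is
#' below a cutoff (default 0.15, the community open-water convention).
#'
#' @param siconc a `forcing_field` of sea-ice concentration.
#' @param mask [region_mask()] or logical matrix.
#' @param cutoff open-water concentration cutoff.
#' @return `data.frame` with `time`, `fraction`, `area_km2`.
#' @export
open_water_fraction <- function(siconc, mask, cutoff = 0.15) {
  m <- .as_mask(mask, siconc$lat, siconc$lon)
  w <- matrix(cell_area(siconc$lat), length(siconc$lat),
              length(siconc$lon))
  nt <- dim(siconc$values)[1]
  res <- t(vapply(seq_len(nt), function(it) {
    sl <- siconc$values[it, , ]
    ok <- m & !is.na(sl)
    if (!any(ok)) return(c(NA_real_, NA_real_))
    open <- ok & sl < cutoff
    c(sum(w[open]) / sum(w[ok]), sum(w[open]))
  }, numeric(2)))
  data.frame(time = siconc$time, fraction = res[, 1], area_km2 = res[, 2])
}

#' Area where light exceeds a threshold
#'
#' Area-weighted extent of mask cells whose band value exceeds the
#' threshold (default the 0.1 W m-2 visual-feeding minimum).
#'
#' @param field list with `values` `[time, lat, lon]`, `lat`, `lon`,
#'   `time` (e.g. [light_band()]).
#' @param mask [region_mask()] or logical matrix.
#' @param threshold threshold in the field's units.
#' @return `data.frame` with `time`, `fraction`, `area_km2`.
#' @export
area_above_light <- function(field, mask, threshold = 0.1) {
  m <- .as_mask(mask, field$lat, field$lon)
  w <- matrix(cell_area(field$lat), length(field$lat), length(field$lon))
  nt <- dim(field$values)[1]
  res <- t(vapply(seq_len(nt), function(it) {
    sl <- field$values[it, , ]
    ok <- m & !is.na(sl)
    if (!any(ok)) return(c(NA_real_, NA_real_))
    lit <- ok & sl > threshold
    c(sum(w[lit]) / sum(w[ok]), sum(w[lit]))
  }, numeric(2)))
  data.frame(time = field$time, fraction = res[, 1], area_km2 = res[, 2])
}
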