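# The radiative-transfer engine: per-cell, per-timestep orchestration of
# clear-sky spectra, cloud adjustment, bias correction, surface albedo
# partitioning (open-water and ice paths) and attenuation, integrated to
# the output bands. Monthly values are the mean of 6 instantaneous
# evaluations 4 h apart in local solar time on the 15th of the month.
# Cells are mutually independent; evaluation is vectorized over cells.

#' RTM configuration
#'
#' @param scenario label recorded in outputs.
#' @param years length-2 span of years to simulate (clipped to forcing
#'   coverage).
#' @param lat_range latitude span of the simulation, degrees N.
#' @param lon_stride take every `lon_stride`-th longitude of the forcing
#'   grid (1 = full resolution); coarser strides make exploratory and
#'   sensitivity runs cheap.
#' @param hours local solar hours of the instantaneous evaluations on the
#'   sampling day.
#' @param sampling_day day of month sampled.
#' @param melt_ponds,wind,chl,use_osa feature toggles: melt-pond albedo
#'   reduction, wind effects (waves + whitecaps), chlorophyll effects
#'   (albedo + attenuation), and the full ocean-surface-albedo scheme
#'   versus a fixed open-water albedo.
#' @param fixed_ocean_albedo open-water albedo used when `use_osa = FALSE`.
#' @param k_snow broadband snow attenuation coefficient, m-1.
#' @param bias_factor multiplicative correction applied to modelled
#'   global irradiance before albedo and attenuation (1 disables).
#' @param layer_depth depth (m) of the chlorophyll-attenuated surface
#'   layer reported as `par_water_layer`.
#' @param spectral [spectral_params()].
#' @param albedo [albedo_params()].
#' @return List of class `rtm_config`.
#' @export
rtm_config <- function(scenario = "historical", years = c(1979, 2100),
                       lat_range = c(60, 85), lon_stride = 1L,
                       hours = seq(0, 20, by = 4), sampling_day = 15L,
                       melt_ponds = TRUE, wind = TRUE, chl = TRUE,
                       use_osa = TRUE, fixed_ocean_albedo = 0.06,
                       k_snow = 20, bias_factor = 1.17, layer_depth = 5,
                       spectral = spectral_params(),
                       albedo = albedo_params()) {
  stopifnot(is.numeric(years), length(years) == 2, years[1] <= years[2],
            lon_stride >= 1, bias_factor > 0, k_snow >= 0)
  structure(list(scenario = scenario, years = years, lat_range = lat_range,
                 lon_stride = as.integer(lon_stride), hours = hours,
                 sampling_day = as.integer(sampling_day),
                 melt_ponds = melt_ponds, wind = wind, chl = chl,
                 use_osa = use_osa, fixed_ocean_albedo = fixed_ocean_albedo,
                 k_snow = k_snow, bias_factor = bias_factor,
                 layer_depth = layer_depth, spectral = spectral,
                 albedo = albedo),
            class = "rtm_config")
}

#' Read an RTM configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [rtm_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return An `rtm_config`.
#' @export
rtm_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(rtm_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(y$spectral)) y$spectral <- do.call(spectral_params, y$spectral)
  if (!is.null(y$albedo)) y$albedo <- do.call(albedo_params, y$albedo)
  do.call(rtm_config, y)
}

# band output names of the engine
LIGHT_BANDS <- c("ghi_interface", "par_interface", "uv_interface",
                 "uvb_interface", "ghi_water", "par_water", "uv_water",
                 "uvb_water", "par_water_layer")

# core: one calendar month for a set of cells.
# cells: data.frame with lat and the 12 forcing variables (wind as uas/vas)
# returns matrix [n, length(LIGHT_BANDS)] plus broadband albedo diagnostic
.rtm_cell_month <- function(date, cells, config, tables) {
  n <- nrow(cells)
  grid <- spectral_grid()
  wl <- grid$wl; nw <- length(wl)
  doy <- as.POSIXlt(date)$yday + 1
  decl <- .declination(doy)
  dist <- .distance_factor(doy)

  w_ghi <- .band_weights("ghi"); w_par <- .band_weights("par")
  w_uv <- .band_weights("uv"); w_uvb <- .band_weights("uvb")
  wmat <- cbind(w_ghi, w_par, w_uv, w_uvb)

  k_ice_vec <- tables$k_ice
  k_ice_vec[is.na(k_ice_vec)] <- 1e6        # fully absorbed beyond cutoff

  acc <- matrix(0, n, length(LIGHT_BANDS),
                dimnames = list(NULL, LIGHT_BANDS))
  refl_sum <- rep(0, n); inc_sum <- rep(0, n)

  for (h in config$hours) {
    ha <- 15 * (h - 12)
    z <- .zenith_deg(cells$lat, decl, ha)
    up <- which(z < 90)
    if (!length(up)) next
    cu <- cells[up, , drop = FALSE]
    mu <- cos(z[up] * pi / 180)

    cs <- .clearsky_matrix(z[up], cu$toz, cu$prw, dist, config$spectral)
    ghi_clear <- cs$dni * mu + cs$dhi
    clt <- cu$clt
    dni <- (1 - clt) * cs$dni
    dhi <- (1 - clt) * cs$dhi +
      clt * config$spectral$overcast_transmittance * ghi_clear
    dni <- dni * config$bias_factor
    dhi <- dhi * config$bias_factor
    i0 <- dni * mu + dhi                     # interface spectrum

    wind <- if (config$wind) sqrt(cu$uas^2 + cu$vas^2) else rep(0, length(up))
    chl_eff <- if (config$chl) cu$chl else rep(0, length(up))
    if (config$use_osa) {
      osa <- .osa_matrix(z[up], wind, chl_eff, wl)
    } else {
      fa <- matrix(config$fixed_ocean_albedo, length(up), nw)
      osa <- list(direct = fa, diffuse = fa)
    }

    # open-water path
    i_open <- (1 - osa$direct) * dni * mu + (1 - osa$diffuse) * dhi

    # ice path: broadband snow/ice albedos, snow then spectral ice decay
    a_o <- rowMeans(0.5 * (osa$direct + osa$diffuse))
    a_ice <- ice_albedo_dry(cu$sithick, a_o, config$albedo)
    a_snow <- rep(config$albedo$a_snow_ice, length(up))
    if (config$melt_ponds) {
      a_ice <- apply_melt_pond(a_ice, cu$tas, config$albedo)
      if (config$albedo$pond_on_snow)
        a_snow <- apply_melt_pond(a_snow, cu$tas, config$albedo)
    }
    t_snow <- exp(-tables$k_snow * cu$sisnthick)
    surf_fac <- cu$sisnconc * (1 - a_snow) * t_snow +
      (1 - cu$sisnconc) * (1 - a_ice)
    t_ice <- exp(-outer(cu$sithick, k_ice_vec))
    i_ice <- i0 * surf_fac * t_ice

    i_water <- (1 - cu$siconc) * i_open + cu$siconc * i_ice

    # chlorophyll-attenuated 0-5 m layer mean
    kz <- outer(chl_eff, tables$aphy) * config$layer_depth
    mean_fac <- ifelse(kz > 1e-12, (1 - exp(-kz)) / kz, 1)
    i_layer <- i_water * mean_fac

    acc[up, c("ghi_interface", "par_interface", "uv_interface",
              "uvb_interface")] <-
      acc[up, c("ghi_interface", "par_interface", "uv_interface",
                "uvb_interface")] + i0 %*% wmat
    acc[up, c("ghi_water", "par_water", "uv_water", "uvb_water")] <-
      acc[up, c("ghi_water", "par_water", "uv_water", "uvb_water")] +
      i_water %*% wmat
    acc[up, "par_water_layer"] <- acc[up, "par_water_layer"] +
      as.numeric(i_layer %*% w_par)

    # energy-weighted broadband albedo diagnostic
    refl <- (1 - cu$siconc) * (osa$direct * dni * mu + osa$diffuse * dhi) +
      cu$siconc * i0 * (cu$sisnconc * a_snow + (1 - cu$sisnconc) * a_ice)
    refl_sum[up] <- refl_sum[up] + as.numeric(refl %*% w_ghi)
    inc_sum[up] <- inc_sum[up] + as.numeric(i0 %*% w_ghi)
  }
  acc <- acc / length(config$hours)
  albedo_bb <- ifelse(inc_sum > 0, refl_sum / inc_sum, NA_real_)
  list(bands = acc, albedo = albedo_bb)
}

#' Light budget of a single cell and month
#'
#' Runs the full per-cell chain (clear sky, clouds, bias, albedo
#' partition, snow/ice/chlorophyll attenuation, band integration) for one
#' grid cell and one month, averaging the configured instantaneous
#' timesteps.
#'
#' @param forcings named list with scalar values of the 12 forcing
#'   variables (`tas, siconc, sisnthick, chl, sithick, sisnconc, clt, uas,
#'   vas, toz, tos, prw`).
#' @param lat cell latitude, degrees N.
#' @param date any `Date` in the month (the engine samples its 15th).
#' @param config [rtm_config()].
#' @return Named list of banded light values (W m-2): GHI/PAR/UV/UV-B at
#'   the atmosphere-surface interface and in-water, the
#'   chlorophyll-attenuated 0-5 m layer-mean PAR, and the broadband
#'   albedo diagnostic. `NA` forcings give an all-`NA` (masked) result.
#' @export
simulate_cell_month <- function(forcings, lat, date,
                                config = rtm_config()) {
  need <- setdiff(FORCING_VARS, names(forcings))
  if (length(need)) stop("missing forcing variables: ",
                         paste(need, collapse = ", "))
  vals <- unlist(forcings[FORCING_VARS])
  if (anyNA(vals)) {
    out <- setNames(rep(NA_real_, length(LIGHT_BANDS) + 1),
                    c(LIGHT_BANDS, "albedo_broadband"))
    return(as.list(out))
  }
  date <- as.Date(date)
  date <- as.Date(sprintf("%s-%02d", format(date, "%Y-%m"),
                          config$sampling_day))
  cells <- as.data.frame(as.list(vals))
  cells$lat <- lat
  tables <- attenuation_tables(k_snow = config$k_snow)
  res <- .rtm_cell_month(date, cells, config, tables)
  out <- as.list(setNames(as.numeric(res$bands[1, ]), LIGHT_BANDS))
  out$albedo_broadband <- res$albedo[1]
  out
}

#' Run the RTM over a forcing set
#'
#' @param forcings named list of the 12 `forcing_field`s on a common grid.
#' @param config [rtm_config()].
#' @param progress print per-year progress to stderr?
#' @return A `light_field_set`: list with `bands` (named list of
#'   `[time, lat, lon]` arrays, W m-2), `albedo_broadband` diagnostic
#'   array, `lat`, `lon`, `time`, the `config`, and `n_skipped` cells
#'   masked for missing forcing.
#' @export
run_rtm <- function(forcings, config = rtm_config(), progress = FALSE) {
  need <- setdiff(FORCING_VARS, names(forcings))
  if (length(need)) stop("configuration error: missing forcings: ",
                         paste(need, collapse = ", "))
  ref <- forcings[[1]]
  for (f in forcings) {
    if (!isTRUE(all.equal(f$lat, ref$lat)) ||
        !isTRUE(all.equal(f$lon, ref$lon)) ||
        length(f$time) != length(ref$time))
      stop("configuration error: forcing grids/times inconsistent")
  }
  yr <- as.integer(format(ref$time, "%Y"))
  t_keep <- which(yr >= config$years[1] & yr <= config$years[2])
  if (!length(t_keep)) stop("configuration error: years outside forcing span")
  lat_keep <- which(ref$lat >= config$lat_range[1] &
                      ref$lat <= config$lat_range[2])
  lon_keep <- seq(1, length(ref$lon), by = config$lon_stride)
  lat <- ref$lat[lat_keep]; lon <- ref$lon[lon_keep]
  time <- ref$time[t_keep]
  nt <- length(time); nlat <- length(lat); nlon <- length(lon)

  tables <- attenuation_tables(k_snow = config$k_snow)
  bands <- lapply(setNames(LIGHT_BANDS, LIGHT_BANDS),
                  function(b) array(NA_real_, c(nt, nlat, nlon)))
  alb <- array(NA_real_, c(nt, nlat, nlon))
  n_skipped <- 0L

  latg <- rep(lat, times = nlon)
  for (it in seq_len(nt)) {
    sl <- lapply(forcings, function(f)
      as.numeric(f$values[t_keep[it], lat_keep, lon_keep]))
    cells <- as.data.frame(sl)
    cells$lat <- latg
    ok <- !Reduce(`|`, lapply(sl, is.na))
    n_skipped <- n_skipped + sum(!ok)
    if (any(ok)) {
      res <- .rtm_cell_month(time[it], cells[ok, , drop = FALSE],
                             config, tables)
      for (b in LIGHT_BANDS) {
        m <- matrix(NA_real_, nlat, nlon)
        m[ok] <- res$bands[, b]
        bands[[b]][it, , ] <- m
      }
      m <- matrix(NA_real_, nlat, nlon)
      m[ok] <- res$albedo
      alb[it, , ] <- m
    }
    if (progress && it %% 12 == 0)
      message(sprintf("rtm: finished %s (%d/%d months)",
                      format(time[it], "%Y"), it, nt))
  }
  structure(list(bands = bands, albedo_broadband = alb, lat = lat,
                 lon = lon, time = time, config = config,
                 n_skipped = n_skipped),
            class = "light_field_set")
}

#' @export
print.light_field_set <- function(x, ...) {
  cat(sprintf("<light_field_set> %d months x %d lat x %d lon; %d cells masked\n",
              length(x$time), length(x$lat), length(x$lon), x$n_skipped))
  cat("  bands:", paste(names(x$bands), collapse = ", "), "\n")
  invisible(x)
}

#' Write a light field set to plain-text gridded files
#'
#' One file per band (`<band>.txt`) in the package's gridded text format.
#'
#' @param x a `light_field_set`.
#' @param dir output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
write_light_fields <- function(x, dir) {
  stopifnot(inherits(x, "light_field_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (b in names(x$bands)) {
    p <- file.path(dir, paste0(b, ".txt"))
    .grid_txt_write(list(variable_id = b, units = "W m-2",
                         scenario = x$config$scenario, model_id = "rtm",
                         realization_id = "r1", lat = x$lat, lon = x$lon,
                         time = x$time, values = x$bands[[b]]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read one gridded text field (forcing or light output)
#'
#' Lower-level reader returning the raw field without forcing-variable
#' validation; useful for light-field outputs.
#'
#' @param path file in the package's gridded text format.
#' @return List with `variable_id`, `units`, `scenario`, `model_id`,
#'   `realization_id`, `lat`, `lon`, `time`, `values`.
#' @export
read_gridded <- function(path) .grid_txt_read(path)

#' Extract one band as a forcing-field-like object for regional analysis
#'
#' @param x a `light_field_set`.
#' @param band one of the band names in `x$bands`.
#' @return List with `values` `[time, lat, lon]`, `lat`, `lon`, `time`.
#' @export
light_band <- function(x, band) {
  stopifnot(inherits(x, "light_field_set"))
  if (!band %in% names(x$bands)) stop("unknown band: ", band)
  list(values = x$bands[[band]], lat = x$lat, lon = x$lon, time = x$time)
}
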