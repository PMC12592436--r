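# Shared fixtures: tiny grids and forcing fields built in code.

tiny_grid <- function(lats = 60:63, lons = 0:3) {
  structure(list(lat = lats, lon = lons), class = "cryo_grid")
}

# constant-valued forcing field on a small grid
tiny_field <- function(variable_id = "tos", value = 1, lats = 60:63,
                       lons = 0:3, years = c(2000, 2000), ...) {
  time <- cryolight:::month_stamps(years[1], years[2])
  vals <- array(value, c(length(time), length(lats), length(lons)))
  forcing_field(variable_id, vals, lats, lons, time, ...)
}

# full 12-variable forcing set on a coarse subgrid, deterministic
tiny_forcing_set <- function(years = c(2000, 2001), seed = 11,
                             scenario = "historical") {
  cfg <- synthetic_forcing_config(scenario, years = years, seed = seed)
  suppressWarnings(generate_synthetic_forcing(cfg))
}

scalar_forcings <- function(...) {
  base <- list(tas = -2, siconc = 0, sisnthick = 0, chl = 0.1,
               sithick = 0, sisnconc = 0, clt = 0.7, uas = 3, vas = 1,
               toz = 330, tos = 1, prw = 5)
  override <- list(...)
  base[names(override)] <- override
  base
}
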