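# Surface albedo: open-ocean spectral albedo (zenith, wind, chlorophyll)
# blended with broadband sea-ice/snow albedo including a thin-ice ramp and
# a melt-pond correction driven by near-surface air temperature.

#' Albedo parameter block
#'
#' Broadband constants of the sea-ice/snow albedo parameterization. The
#' thick-ice and snow-covered-ice values represent annual average surface
#' conditions (the corresponding pure-surface albedos, 0.73 for ice and
#' 0.96 for snow, are retained as metadata only).
#'
#' @param a_ice_thick albedo of thick (> `h_ref`) bare sea ice.
#' @param a_snow_ice albedo of snow-covered sea ice.
#' @param c_fh steepness of the thin-ice arctangent ramp.
#' @param h_ref ice thickness (m) above which ice is optically thick.
#' @param pond_dalb maximum melt-pond albedo reduction.
#' @param pond_onset_T air temperature (degC) at which ponds start to form.
#' @param pond_on_snow apply the pond correction to snow-covered ice too?
#' @return List of class `albedo_params`.
#' @export
albedo_params <- function(a_ice_thick = 0.52, a_snow_ice = 0.65,
                          c_fh = 5.0, h_ref = 0.5, pond_dalb = 0.075,
                          pond_onset_T = -1.0, pond_on_snow = TRUE) {
  stopifnot(a_ice_thick >= 0, a_ice_thick <= 1,
            a_snow_ice >= 0, a_snow_ice <= 1)
  structure(list(a_ice_thick = a_ice_thick, a_snow_ice = a_snow_ice,
                 c_fh = c_fh, h_ref = h_ref, pond_dalb = pond_dalb,
                 pond_onset_T = pond_onset_T, pond_on_snow = pond_on_snow,
                 a_ice_pure = 0.73, a_snow_pure = 0.96),
            class = "albedo_params")
}

#' Per-cell surface state
#'
#' Everything the albedo and attenuation calculations need at one grid
#' cell: ice and snow fractions and thicknesses, air temperature, scalar
#' wind speed and chlorophyll. `sisnconc` is interpreted as the
#' snow-covered fraction of the ice-covered area.
#'
#' @param siconc,sisnconc fractions in \[0,1\].
#' @param sithick,sisnthick thicknesses, m.
#' @param tas near-surface air temperature, degC.
#' @param wind scalar wind speed, m s-1 (e.g. `sqrt(uas^2 + vas^2)`).
#' @param chl chlorophyll-a, mg m-3.
#' @return List of class `surface_state`.
#' @export
surface_state <- function(siconc = 0, sisnconc = 0, sithick = 0,
                          sisnthick = 0, tas = 0, wind = 0, chl = 0) {
  stopifnot(siconc >= 0, siconc <= 1, sisnconc >= 0, sisnconc <= 1,
            sithick >= 0, sisnthick >= 0, wind >= 0, chl >= 0)
  structure(list(siconc = siconc, sisnconc = sisnconc, sithick = sithick,
                 sisnthick = sisnthick, tas = tas, wind = wind, chl = chl),
            class = "surface_state")
}

# ---- open ocean ----------------------------------------------------------

# unpolarized Fresnel reflectance at incidence theta (deg), n = 1.34
.fresnel <- function(theta_deg, n = 1.34) {
  th <- pmin(pmax(theta_deg, 0), 89.999) * pi / 180
  st <- sin(th) / n
  tt <- asin(pmin(st, 1))
  rs <- (sin(th - tt) / sin(th + tt))^2
  rp <- (tan(th - tt) / tan(th + tt))^2
  r <- 0.5 * (rs + rp)
  r[theta_deg < 1e-6] <- ((n - 1) / (n + 1))^2
  r
}

# diffuse (hemispherically averaged) Fresnel reflectance, computed once
.fresnel_diffuse <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      th <- seq(0.25, 89.75, by = 0.5) * pi / 180
      r <- .fresnel(th * 180 / pi)
      val <<- sum(r * cos(th) * sin(th)) / sum(cos(th) * sin(th))
    }
    val
  }
})

# water-leaving reflectance: bb/(a+bb) weighting with pure-seawater
# absorption and molecular + chlorophyll-driven particulate backscatter
.water_leaving <- function(wl, chl) {
  b_w <- 0.0038 * (550 / wl)^4.32
  b_bp <- 0.002 * chl^0.62
  bb <- 0.5 * b_w + b_bp
  0.15 * bb / (.a_seawater(wl) + bb)
}

# 7-point Gauss-Hermite nodes/weights (physicists' convention)
.gh7 <- list(
  x = c(-2.6519613568352334, -1.6735516287674714, -0.8162878828589647, 0,
        0.8162878828589647, 1.6735516287674714, 2.6519613568352334),
  w = c(0.0009717812450995, 0.0545155828191271, 0.4256072526101278,
        0.8102646175568073, 0.4256072526101278, 0.0545155828191271,
        0.0009717812450995))

# seawater absorption anchors (m-1), UV through near-infrared
.a_seawater <- local({
  cache <- NULL
  function(wl) {
    if (is.null(cache)) {
      anch <- matrix(c(
        200, 3.07, 250, 0.56, 300, 0.15, 320, 0.055, 340, 0.0325,
        350, 0.025, 380, 0.011, 400, 0.0066, 420, 0.0045, 440, 0.0064,
        460, 0.0092, 480, 0.0127, 500, 0.0204, 520, 0.0409, 540, 0.0474,
        560, 0.0619, 580, 0.09, 600, 0.22, 620, 0.276, 640, 0.33,
        660, 0.40, 680, 0.47, 700, 0.62, 720, 1.17, 740, 2.13, 760, 2.55,
        780, 2.29, 800, 2.02, 850, 4.3, 900, 6.8, 950, 29, 1000, 36,
        1100, 17, 1200, 104, 1300, 110, 1400, 1200, 1600, 670, 1900, 6000,
        2200, 2800, 2700, 8000), ncol = 2, byrow = TRUE)
      cache <<- list(anch = anch)
    }
    .interp_log(wl, cache$anch[, 1], cache$anch[, 2])
  }
})

#' Spectral open-ocean surface albedo
#'
#' Direct and diffuse albedo of an ice-free ocean surface as a function of
#' solar zenith angle, wind speed and chlorophyll. The scheme combines
#' (i) specular Fresnel reflection averaged over a wind-dependent
#' Cox--Munk wave-slope distribution, (ii) a wind-driven whitecap fraction
#' with a spectrally declining foam albedo, and (iii) a water-leaving
#' reflectance term depending on seawater and chlorophyll absorption and
#' backscattering (chlorophyll darkens blue wavelengths).
#'
#' @param geom `solar_geometry`.
#' @param wind scalar wind speed, m s-1.
#' @param chl chlorophyll-a concentration, mg m-3.
#' @param grid [spectral_grid()].
#' @return List with `direct` and `diffuse` spectral albedo vectors in
#'   \[0,1\] on the grid's wavelengths.
#' @export
osa_spectral <- function(geom, wind = 0, chl = 0, grid = spectral_grid()) {
  stopifnot(inherits(geom, "solar_geometry"), wind >= 0, chl >= 0)
  wl <- grid$wl
  z <- min(geom$zenith, 89.999)

  # specular: Fresnel over Gaussian tilt distribution (Cox-Munk slopes)
  mss <- 0.003 + 0.00512 * min(wind, 15)
  sig <- atan(sqrt(mss / 2)) * 180 / pi       # one-component tilt sd, deg
  gh <- .gh7
  tilts <- sqrt(2) * sig * gh$x
  a_spec_dir <- sum(gh$w * .fresnel(pmin(pmax(z + tilts, 0), 89.9))) /
    sum(gh$w)
  a_spec_dif <- .fresnel_diffuse()

  # whitecaps
  f_wc <- min(3.84e-6 * wind^3.41, 0.30)
  a_wc <- 0.55 * pmax(1 - 0.7 * pmax(wl - 400, 0) / 2300, 0.2)

  # water-leaving reflectance: chlorophyll enters through particulate
  # backscatter, so more chlorophyll brightens the surface slightly
  a_wl <- .water_leaving(wl, chl)

  direct <- (1 - f_wc) * (a_spec_dir + a_wl) + f_wc * a_wc
  diffuse <- (1 - f_wc) * (a_spec_dif + a_wl) + f_wc * a_wc
  list(direct = pmin(pmax(direct, 0), 1),
       diffuse = pmin(pmax(diffuse, 0), 1))
}

# ---- sea ice and snow ----------------------------------------------------

#' Thin-ice blending fraction
#'
#' Asymptotic thickness ramp
#' `f_h = min(atan(c_fh * h) / atan(c_fh * 0.5), 1)`: 0 for open water,
#' 1 for ice at least 0.5 m thick.
#'
#' @param h ice thickness, m (vectorized).
#' @param params [albedo_params()].
#' @return Fraction in \[0,1\].
#' @export
thin_ice_blend_fh <- function(h, params = albedo_params()) {
  if (any(h < 0)) stop("parameter error: ice thickness must be nonnegative")
  pmin(atan(params$c_fh * h) / atan(params$c_fh * params$h_ref), 1)
}

#' Dry albedo of (possibly thin) bare sea ice
#'
#' `a_dry = a_o * (1 - f_h) + a_ice_thick * f_h`: blends the open-ocean
#' albedo into the thick-ice value as ice thickens.
#'
#' @param h ice thickness, m.
#' @param a_o open-ocean (broadband) albedo underneath/around the ice.
#' @param params [albedo_params()].
#' @return Albedo between `a_o` and `a_ice_thick`.
#' @export
ice_albedo_dry <- function(h, a_o, params = albedo_params()) {
  stopifnot(all(a_o >= 0), all(a_o <= 1))
  fh <- thin_ice_blend_fh(h, params)
  a_o * (1 - fh) + params$a_ice_thick * fh
}

#' Melt-pond (wet) albedo correction
#'
#' Ponds forming when the air warms above `pond_onset_T` reduce the dry
#' albedo by up to `pond_dalb`, ramping linearly from no reduction at
#' -1 degC to the full reduction at 0 degC and above.
#'
#' @param a_dry dry albedo in \[0,1\].
#' @param tas near-surface air temperature, degC.
#' @param params [albedo_params()].
#' @return Wet albedo, never below 0.
#' @export
apply_melt_pond <- function(a_dry, tas, params = albedo_params()) {
  stopifnot(all(a_dry >= 0), all(a_dry <= 1))
  ramp <- pmin(pmax(tas - params$pond_onset_T, 0), 1)
  pmax(a_dry - params$pond_dalb * ramp, 0)
}

#' Composite spectral albedo of a grid cell
#'
#' Area-weighted combination of open water, bare ice and snow-covered ice:
#' `alpha(lambda) = (1 - siconc) * OSA(lambda) +
#'  siconc * ((1 - sisnconc) * a_wet_ice + sisnconc * a_snow)`.
#' Ice and snow albedos are broadband constants applied flat across the
#' spectrum; both receive the melt-pond correction when the air is warm
#' (snow only if `params$pond_on_snow`).
#'
#' @param state [surface_state()].
#' @param osa open-water spectral albedo from [osa_spectral()].
#' @param params [albedo_params()].
#' @param melt_ponds logical sensitivity toggle.
#' @return List with `direct` and `diffuse` spectral albedo vectors plus
#'   scalar components `a_ice` and `a_snow` used for the ice fraction.
#' @export
composite_cell_albedo <- function(state, osa, params = albedo_params(),
                                  melt_ponds = TRUE) {
  stopifnot(inherits(state, "surface_state"))
  # broadband open-ocean albedo entering the thin-ice blend
  a_o <- mean(0.5 * (osa$direct + osa$diffuse))
  a_ice <- ice_albedo_dry(state$sithick, a_o, params)
  a_snow <- params$a_snow_ice
  if (melt_ponds) {
    a_ice <- apply_melt_pond(a_ice, state$tas, params)
    if (params$pond_on_snow)
      a_snow <- apply_melt_pond(a_snow, state$tas, params)
  }
  ice_term <- (1 - state$sisnconc) * a_ice + state$sisnconc * a_snow
  list(direct = (1 - state$siconc) * osa$direct + state$siconc * ice_term,
       diffuse = (1 - state$siconc) * osa$diffuse + state$siconc * ice_term,
       a_ice = a_ice, a_snow = a_snow)
}

# vectorized open-ocean albedo over cells: returns [n, nw] matrices
.osa_matrix <- function(zenith, wind, chl, wl) {
  n <- length(zenith)
  nw <- length(wl)
  z <- pmin(zenith, 89.999)
  wind <- rep_len(pmin(wind, 15), n)
  chl <- rep_len(chl, n)

  mss <- 0.003 + 0.00512 * wind
  sig <- atan(sqrt(mss / 2)) * 180 / pi
  gh <- .gh7
  th <- pmin(pmax(outer(z, rep(1, 7)) +
                    outer(sqrt(2) * sig, gh$x), 0), 89.9)
  rfl <- matrix(.fresnel(th), n, 7)
  a_spec_dir <- as.numeric(rfl %*% gh$w) / sum(gh$w)
  a_spec_dif <- .fresnel_diffuse()

  f_wc <- pmin(3.84e-6 * wind^3.41, 0.30)
  a_wc <- 0.55 * pmax(1 - 0.7 * pmax(wl - 400, 0) / 2300, 0.2)

  b_w <- 0.0038 * (550 / wl)^4.32
  asw <- .a_seawater(wl)
  bb <- 0.5 * matrix(b_w, n, nw, byrow = TRUE) + 0.002 * chl^0.62
  a_wl <- 0.15 * bb / (matrix(asw, n, nw, byrow = TRUE) + bb)

  awc_mat <- matrix(a_wc, n, nw, byrow = TRUE)
  direct <- (1 - f_wc) * (a_spec_dir + a_wl) + f_wc * awc_mat
  diffuse <- (1 - f_wc) * (a_spec_dif + a_wl) + f_wc * awc_mat
  list(direct = pmin(pmax(direct, 0), 1),
       diffuse = pmin(pmax(diffuse, 0), 1))
}
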