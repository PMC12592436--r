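# Attenuation of post-albedo light through snow, sea ice and chlorophyll,
# band integration and unit conversions. Snow attenuates all wavelengths
# with one broadband coefficient; ice attenuates spectrally on 200-1000 nm
# (longer wavelengths are treated as fully absorbed under ice);
# chlorophyll attenuates via Beer-Lambert with a chlorophyll-specific
# absorption spectrum over a 0-5 m surface layer.

.att_env <- new.env(parent = emptyenv())

.read_coef_table <- function(path) {
  d <- read.delim(path, comment.char = "#")
  if (ncol(d) < 2) stop("coefficient table needs two columns")
  names(d)[1:2] <- c("wl", "k")
  if (any(d$k < 0)) stop("coefficients must be nonnegative")
  d
}

#' Attenuation coefficient tables
#'
#' Loads the broadband snow coefficient, the spectral sea-ice absorption
#' table (200--1000 nm) and the chlorophyll-specific absorption table, and
#' interpolates the spectral tables onto the working 10 nm grid. The
#' packaged default tables are author-constructed representative spectra
#' (see `inst/extdata/*_synthetic.tsv`); user tables in the same
#' two-column tab-separated format can be substituted.
#'
#' @param k_snow broadband snow attenuation coefficient, m-1.
#' @param k_ice_path,aphy_path optional paths to replacement tables
#'   (tab-separated: wavelength_nm, coefficient).
#' @param nir_cutoff_nm wavelengths above this are treated as fully
#'   absorbed by ice.
#' @return List of class `attenuation_tables` with `k_snow`, `k_ice`
#'   (per-wavelength, NA above the cutoff) and `aphy` (m^2 per mg chl,
#'   0 outside the tabulated range) on [spectral_grid()] wavelengths.
#' @export
attenuation_tables <- function(k_snow = 20, k_ice_path = NULL,
                               aphy_path = NULL, nir_cutoff_nm = 1000) {
  if (k_snow < 0) stop("k_snow must be nonnegative")
  wl <- spectral_grid()$wl
  if (is.null(k_ice_path))
    k_ice_path <- system.file("extdata", "k_ice_synthetic.tsv",
                              package = "cryolight", mustWork = TRUE)
  if (is.null(aphy_path))
    aphy_path <- system.file("extdata", "aphy_chl_synthetic.tsv",
                             package = "cryolight", mustWork = TRUE)
  ki <- .read_coef_table(k_ice_path)
  if (min(ki$wl) > 200 || max(ki$wl) < 1000)
    stop("k_ice table must cover 200-1000 nm")
  k_ice <- approx(ki$wl, ki$k, xout = wl, rule = 2)$y
  k_ice[wl > nir_cutoff_nm] <- NA_real_   # fully absorbed
  ap <- .read_coef_table(aphy_path)
  aphy <- approx(ap$wl, ap$k, xout = wl, rule = 1)$y
  aphy[is.na(aphy)] <- 0
  structure(list(k_snow = k_snow, k_ice = k_ice, aphy = aphy,
                 nir_cutoff_nm = nir_cutoff_nm,
                 k_ice_path = k_ice_path, aphy_path = aphy_path),
            class = "attenuation_tables")
}

.default_tables <- function() {
  if (is.null(.att_env$tab)) .att_env$tab <- attenuation_tables()
  .att_env$tab
}

# chlorophyll-specific absorption on arbitrary wavelengths (used by the
# ocean-albedo water-leaving term as well)
.aphy_on <- function(wl) {
  tab <- .default_tables()
  gwl <- spectral_grid()$wl
  out <- approx(gwl, tab$aphy, xout = wl, rule = 1)$y
  out[is.na(out)] <- 0
  out
}

#' Broadband transmittance of a snow layer
#'
#' `T = exp(-k_snow * h_snow)`, identical at all wavelengths.
#'
#' @param h_snow snow thickness, m.
#' @param tables [attenuation_tables()].
#' @return Transmittance in \[0,1\] (vectorized).
#' @export
snow_transmittance <- function(h_snow, tables = .default_tables()) {
  if (any(h_snow < 0)) stop("parameter error: negative snow thickness")
  exp(-tables$k_snow * h_snow)
}

#' Spectral transmittance of a sea-ice layer
#'
#' `T(lambda) = exp(-k(lambda) * h_ice)` on 200--1000 nm; wavelengths
#' beyond the table's near-infrared cutoff are fully absorbed (T = 0).
#'
#' @param h_ice ice thickness, m.
#' @param grid [spectral_grid()].
#' @param tables [attenuation_tables()].
#' @return Transmittance vector on the grid's wavelengths.
#' @export
ice_transmittance <- function(h_ice, grid = spectral_grid(),
                              tables = .default_tables()) {
  stopifnot(h_ice >= 0)
  tt <- exp(-tables$k_ice * h_ice)
  tt[is.na(tt)] <- 0
  tt
}

#' Chlorophyll attenuation over a surface layer
#'
#' Beer--Lambert decay with coefficient `aphy(lambda) * chl`. Returns both
#' the spectrum at the bottom of the layer and the analytic layer mean
#' `(1 - exp(-kappa z)) / (kappa z)` scaling per wavelength, which is
#' independent of the vertical chlorophyll distribution within the layer.
#'
#' @param irr spectral irradiance vector on [spectral_grid()] wavelengths
#'   (any units).
#' @param chl chlorophyll-a, mg m-3.
#' @param depth layer thickness, m.
#' @param tables [attenuation_tables()].
#' @return List with `bottom` and `layer_mean` spectra; `chl = 0` returns
#'   the input unchanged.
#' @export
chl_attenuation <- function(irr, chl, depth = 5,
                            tables = .default_tables()) {
  stopifnot(chl >= 0, depth > 0)
  kappa <- tables$aphy * chl
  kz <- kappa * depth
  bottom <- irr * exp(-kz)
  mean_fac <- ifelse(kz > 1e-12, (1 - exp(-kz)) / kz, 1)
  list(bottom = bottom, layer_mean = irr * mean_fac)
}

#' Band integral of a spectrum
#'
#' Integrates a spectral density over a named band by overlap-weighted bin
#' sums: each wavelength is the center of a 10 nm bin and the integral
#' counts the part of each bin inside the band, so a flat
#' 1 W m-2 nm-1 spectrum over 400--700 nm integrates to exactly
#' 300 W m-2.
#'
#' @param irr spectral density on [spectral_grid()] wavelengths
#'   (W m-2 nm-1).
#' @param band `"ghi"` (200--2700), `"par"` (400--700), `"uv"` (280--400),
#'   `"uvb"` (280--315), or a numeric `c(lo, hi)` in nm.
#' @param grid [spectral_grid()].
#' @return Band-integrated irradiance, W m-2.
#' @export
band_integrate <- function(irr, band = "par", grid = spectral_grid()) {
  rng <- if (is.character(band)) {
    if (!band %in% names(BAND_RANGES))
      stop("parameter error: unknown band '", band, "'")
    BAND_RANGES[[band]]
  } else {
    stopifnot(is.numeric(band), length(band) == 2, band[1] < band[2])
    band
  }
  wl <- grid$wl
  lo <- pmax(wl - 5, rng[1]); hi <- pmin(wl + 5, rng[2])
  w <- pmax(hi - lo, 0)
  sum(irr * w)
}

# band weights vector (used by the vectorized engine)
.band_weights <- function(band, grid = spectral_grid()) {
  rng <- BAND_RANGES[[band]]
  wl <- grid$wl
  pmax(pmin(wl + 5, rng[2]) - pmax(wl - 5, rng[1]), 0)
}

#' Convert PAR irradiance to photon flux
#'
#' Multiplies the 400--700 nm band irradiance by the quantum conversion
#' 4.57 umol photons s-1 W-1, so the 0.1 W m-2 visual-feeding threshold
#' corresponds to 0.457 umol photons m-2 s-1.
#'
#' @param e_par PAR irradiance, W m-2.
#' @param factor conversion factor, umol s-1 W-1.
#' @return Photon flux, umol photons m-2 s-1.
#' @export
par_to_photon_flux <- function(e_par, factor = 4.57) {
  stopifnot(all(e_par >= 0))
  e_par * factor
}

#' Apply the global-irradiance bias factor
#'
#' Uniform multiplicative correction of modelled shortwave irradiance
#' (default 1.17), applied to the spectrum before albedo and attenuation.
#'
#' @param x a `spectral_irradiance`, or a numeric vector/list of band
#'   values.
#' @param factor positive scaling factor; 1 disables the correction.
#' @return Same type as `x`, scaled.
#' @export
apply_ghi_bias <- function(x, factor = 1.17) {
  if (!is.numeric(factor) || factor <= 0)
    stop("parameter error: bias factor must be positive")
  if (inherits(x, "spectral_irradiance")) {
    x$dni <- x$dni * factor
    x$dhi <- x$dhi * factor
    return(x)
  }
  if (is.list(x)) return(lapply(x, function(v) v * factor))
  x * factor
}
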