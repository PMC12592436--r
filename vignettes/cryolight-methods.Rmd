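---
title: "Modelling spectral light in seasonally ice-covered seas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spectral light in seasonally ice-covered seas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryolight)
```

## Overview

`cryolight` converts monthly gridded climate forcings into spectrally
resolved shortwave irradiance at and just below the surface of polar
oceans, and derives ecosystem-relevant metrics from the resulting light
and temperature fields. The chain is, per grid cell and month:

1. **Clear-sky spectral irradiance** (200–2700 nm at 10 nm): direct and
   diffuse components from solar geometry, total column ozone and
   precipitable water.
2. **Cloud opacity adjustment**: the partly cloudy sky is the
   cloud-fraction-weighted average of the clear sky and a fully diffuse
   overcast sky.
3. **Bias correction**: a uniform multiplicative factor (default 1.17) on
   the global irradiance, applied before any surface interaction.
4. **Surface albedo partition**: a spectral open-water albedo (zenith,
   wind, chlorophyll) combined, by ice fraction, with broadband bare-ice
   and snow-covered-ice albedos including a thin-ice ramp and a melt-pond
   correction.
5. **Attenuation**: broadband exponential decay through snow, spectral
   exponential decay through ice (200–1000 nm; longer wavelengths treated
   as fully absorbed under ice), and chlorophyll Beer–Lambert decay over
   a 0–5 m surface layer.
6. **Band integration** to GHI (200–2700 nm), PAR (400–700 nm), UV
   (280–400 nm) and UV-B (280–315 nm), with an energy-to-photon
   conversion of 4.57 μmol s⁻¹ W⁻¹ for PAR.

Monthly values are the mean of six instantaneous evaluations four hours
apart in **local solar time** on the 15th of the month. Anchoring the
timesteps in local solar time makes the zenith angle a function of
latitude and hour only, which keeps cells independent and the
computation vectorizable; it is recorded here because UTC anchoring
would phase-shift the diurnal sampling by longitude.

## The clear-sky spectral model

The model follows the classical simple-spectral-model transmittance
formulation. The direct beam at wavelength $\lambda$ is

$$I_d(\lambda) = E_0(\lambda)\, D\, T_R T_A T_W T_O T_U,$$

with $E_0$ the extraterrestrial spectrum, $D$ the Sun–Earth distance
factor, and Rayleigh, aerosol, water-vapour, ozone and mixed-gas
transmittances. Diffuse irradiance is built from Rayleigh- and
aerosol-scattered terms plus a ground-reflection term, with an empirical
spectral correction below 450 nm. Aerosols use an Angström law
(optical depth 0.10 at 500 nm, exponent 1.14, single-scattering albedo
0.945 at 400 nm, asymmetry 0.65); all defaults live in
`spectral_params()` and are recorded in configurations.

The coefficient tables are compiled by the package authors from standard
literature anchor values: the extraterrestrial spectrum is normalized so
its 200–2700 nm integral is 1302 W m⁻² (the fraction of the 1361 W m⁻²
total solar irradiance carried by that range); ozone absorption spans
the Hartley, Huggins and Chappuis bands; water vapour and mixed gases
(O₂ A/B, weak CO₂) use band anchors with a 1.6× enhancement accounting
for line structure unresolved by 10 nm band sampling of the saturating
band-transmittance formula. Validation in the test suite compares
broadband global irradiance against an independent broadband clear-sky
closed form; agreement is within 2–3% at zenith angles 30–80°.

Two properties matter most downstream and are asserted as invariants:
UV-B at the surface decreases strictly with the ozone column, and PAR is
nearly insensitive to it. Note that the small Chappuis visible band
makes PAR respond at the ~2% level to a doubling of the column; this is
a physical feature of ozone absorption, not a numerical artifact.

Cloud treatment: `diffuse_fraction()` provides the Campbell–Norman
diffuse-vs-direct fraction (clear-sky transmittance 0.7, blended
linearly to 1 at full overcast) as a diagnostic, and
`apply_cloud_opacity()` mixes the clear sky with an overcast sky that is
fully diffuse, carries the spectral shape of clear-sky global
irradiance, and transmits 30% of the clear-sky broadband energy
(`overcast_transmittance`, configurable). At zero cloud the spectrum is
returned unchanged; at full cover the direct beam vanishes.

Ozone input: the `toz` forcing variable is used directly when present.
When only a mixing-ratio profile is available,
`vmr_profile_to_dobson()` converts it with the trapezoidal pressure
integral $toz = 10\,\frac{R T_0}{g_0 P_0}\sum_i \tfrac12 (VMR_i +
VMR_{i+1})(p_i - p_{i+1})$ (prefactor 0.78977 DU per ppm·hPa); the
conversion is exactly linear in the mixing ratio.

## Surface albedo

**Open water.** `osa_spectral()` composes three contributions:
specular Fresnel reflection (refractive index 1.34) averaged over a
wind-dependent Cox–Munk wave-slope distribution (mean-square slope
$0.003 + 0.00512\,U$) with 7-point Gauss–Hermite quadrature; a
whitecap fraction $3.84\times10^{-6} U^{3.41}$ with a spectrally
declining foam albedo (0.55 in the visible); and a water-leaving
reflectance $0.15\, b_b/(a_w + b_b)$ from pure-seawater absorption,
molecular backscatter and a chlorophyll-driven particulate backscatter
$0.002\,\mathrm{chl}^{0.62}$. Chlorophyll therefore brightens the
surface slightly (backscatter) while darkening the water column
(absorption), so removing chlorophyll effects increases in-water light
through both albedo and attenuation — the direction the sensitivity
suite asserts. The diffuse specular term is the hemispherically averaged
Fresnel reflectance (≈0.066). This scheme is the package's own
construction; the properties it must guarantee are bounds in
[0,1], the Fresnel limit at normal incidence, and monotone growth of the
direct albedo with zenith angle.

**Sea ice and snow.** Broadband constants applied flat across the
spectrum: thick bare ice 0.52, snow-covered ice 0.65 (annual average
surface conditions; the pure-surface values 0.73/0.96 are retained as
metadata only). Thin ice blends from the open-water albedo via
$f_h = \min(\arctan(5h)/\arctan(2.5), 1)$, reaching the thick-ice value
at 0.5 m. Melt ponds reduce albedo by up to 0.075, ramping linearly
between −1 °C and 0 °C air temperature; the reduction applies to both
bare and snow-covered ice (toggleable via `pond_on_snow`), since the
parameterization does not separate pond formation by surface type. The
pond correction is written as a *reduction*: the alternative sign
(raising albedo when warm) would contradict the documented sensitivity
direction that ponds increase light penetration.

`sisnconc` is interpreted as the snow-covered fraction *of the
ice-covered area*; the cell albedo is
$(1-c_i)\,\alpha_{ocean}(\lambda) + c_i[(1-c_s)\alpha_{ice} +
c_s\alpha_{snow}]$.

## Attenuation and bands

Snow attenuates with a single broadband coefficient
$k_{snow} = 20\ \mathrm{m^{-1}}$ at all wavelengths (observed values
span roughly 4.3–40 m⁻¹; 5.9 m⁻¹ is the conventional alternative used in
the sensitivity suite). Ice uses a spectral coefficient table on
200–1000 nm; wavelengths beyond 1000 nm are treated as fully absorbed
under ice (no published coefficients there, and near-infrared absorption
in ice and water is very strong). The shipped tables
(`inst/extdata/k_ice_synthetic.tsv`, `aphy_chl_synthetic.tsv`) are
author-constructed representative spectra — a blue transmission maximum
near 450–500 nm for ice, and the canonical 440/676 nm absorption peaks
for chlorophyll — clearly labelled synthetic; users substitute measured
tables in the same two-column format for production work.

Chlorophyll attenuation over the 0–5 m layer uses the analytic layer
mean $(1 - e^{-\kappa z})/(\kappa z)$ per wavelength, which is
independent of the vertical distribution of chlorophyll within the
layer. The primary in-water output is the irradiance just below the
interface (or ice underside); the chlorophyll-attenuated layer mean is a
secondary output (`par_water_layer`).

Band integrals use overlap-weighted 10 nm bin sums, so a flat
1 W m⁻² nm⁻¹ spectrum integrates to exactly 300 W m⁻² over 400–700 nm;
this convention is exactly reproducible and symmetric at band edges.

## The synthetic forcing generator

The generator is first-class, tested code that defines the study
conditions under which the pipeline is exercised: every variable is a
latitude-dependent seasonal climatology plus a scenario-dependent linear
trend per century plus optional Gaussian noise, clamped to physical
bounds (with the clamp count reported). Key conditions: a winter sea-ice
maximum with a poleward gradient; warming of `tas`/`tos` (historical
+1.5/+1.0, intermediate scenario +4/+3, high scenario +7/+5 °C per
century) with matching declines of ice concentration and ice/snow
thickness; ozone recovery (+25/+45 DU per century under the future
scenarios) after a weak historical decline; near-constant cloud cover
around 0.85; and a spring chlorophyll bloom (Gaussian in day-of-year,
peaking later at higher latitude) whose peak advances 4 days per decade
by default. Trend magnitudes are round numbers chosen to sit in the
range high-latitude projections span; because trends enter linearly,
decadal differences have closed forms that the tests exploit.

What the generator does **not** emulate: spatial weather correlation
(noise is white in space), interannual modes, scenario nonlinearity
(tipping-point behaviour), or realistic land/coast masks. Passing tests
therefore demonstrate correctness of the radiative and statistical
machinery under controlled conditions, not fidelity of any specific
regional magnitude from real climate-model archives.

## Ensemble weighting

`compute_diagnostics()` reduces a temperature field to per-cell
climatology, least-squares trend and detrended standard deviation;
`compute_distances()` forms area-weighted RMSEs over a 66–80°N window,
normalizes each diagnostic by its ensemble-median distance (the
combination weights among the three diagnostics being otherwise
unspecified, the normalized mean is the package's documented choice),
and averages realizations of the same model before distances.
`compute_weights()` applies the performance/independence form and
normalizes the weights to sum to one — the raw form is unnormalized and
cannot be used directly for averaging. The shape parameters default to
the ensemble medians of the distances (overridable); with a single
perfect model the weight is 1, with $M$ identical models each raw weight
is $1/M$, and duplicating a member strictly reduces its weight.

## Regional metrics and the biology model

Area weighting uses the spherical cell area
$\delta A = R^2 \delta\varphi\, \delta\lambda \cos\varphi$ (R = 6371 km).
The two ecosystem masks are approximate boxes (Northern Bering–Chukchi:
64–75°N, 175–205°E; Barents: 70–80°N, 20–55°E), centred at the
documented 69.5°N and 75.0°N; user masks are accepted everywhere.
Open water is sea-ice concentration below 0.15 (community convention).
Rolling means are centred with shrinking windows at the edges.
Threshold-duration metrics treat the monthly series as piecewise linear
between month centres; each half-year window spans exactly six months
from the January (July) centre, so a crossing midway between two months
yields half-month values.

Thermal performance curves are scaled-beta forms over the thermal window
$[T_{low}, T_{high}]$ with exponents chosen so the maximum falls exactly
at the tabulated optimum with the tabulated peak: polar cod eggs
(optimum 0.2 °C, peak 88%, window −2..4.5 °C), polar cod juveniles
(7.5 °C, 1.5 %/d, −1..12 °C), Atlantic cod eggs (4.3 °C, 93%) and
juveniles (14 °C, 4.7 %/d), walleye pollock eggs (3.6 °C, 83%) and
juveniles (13 °C, 3.0 %/d). The lower egg limit for polar cod is set at
−2 °C, near the freezing point of seawater; the boreal species' limits
default to literature-range values and are all overridable via
`species_params(file=)`. The polar cod egg shape parameter (0.11 °C⁻¹)
is calibrated so the curve reproduces the published survival decline
from 85% under 1.2–2 °C winter warming; the other curves use a moderate
default (0.3 °C⁻¹) in the absence of published anchors. Egg metrics use
February–April temperatures and juvenile metrics May–July by default
(switchable), the months being ambiguous across sources. Light does not
enter the biology model directly; light-based feeding-season metrics
live in the regional-metrics module.

## Numerical choices and degenerate inputs

* Zenith angles ≥ 90° short-circuit to zero spectra; air mass formulas
  are clamped at 89.999°.
* Fractions are validated into [0,1]; thicknesses and chlorophyll must
  be nonnegative; the ozone column must be positive.
* Cells with any missing forcing are masked and counted, never filled.
* Bilinear regridding wraps longitude over 0/360 and renormalizes
  weights over valid neighbours when source cells are masked; a target
  cell with no valid neighbour is `NA`.
* The engine is deterministic for a fixed configuration; cells are
  independent, so evaluation order cannot affect results.
* Text serialization writes 17 significant digits, so doubles round-trip
  bit-exactly.

## Problem sizes

The test and acceptance runs use a longitude-subsampled grid (every
20th longitude, 26 latitudes, 468 cells) for the 10-year sensitivity
protocol, and 5-latitude × 6-longitude subregions for smoke tests. These
sizes were chosen to exercise every code path — polar night, partial
ice, open water — while keeping a full sensitivity sweep (baseline plus
four toggles) in the low minutes on a single core. Full-resolution runs
(26 × 360 cells, 122 years) use the identical code path via
`rtm_config(lon_stride = 1)`.

## Known limitations

* One-dimensional radiative transfer: no cloud layering or 3-D effects;
  clouds act through a single opacity factor.
* The spectral coefficient tables are literature-anchored
  reconstructions, adequate for band-level energetics (validated to a
  few percent broadband) but not for line-level spectroscopy.
* The ice and chlorophyll absorption tables shipped are representative
  synthetic spectra, not measurements.
* No attenuation by cDOM, non-algal particles or ice algae; no
  water-column light profile beyond the 0–5 m layer mean.
* The biology model is temperature-only; no bioenergetics, prey
  coupling, or movement.
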