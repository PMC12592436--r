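# cryolight

Projected losses of Arctic sea ice and snow are changing how much
sunlight enters polar surface waters — and with it the conditions for
phytoplankton, zooplankton and the early life stages of fish.
`cryolight` is an R toolkit for quantifying that change: it converts
monthly gridded climate forcings (clouds, ozone, water vapour, sea ice,
snow, wind, chlorophyll-a, temperature) into spectrally resolved
shortwave irradiance at and just below the ocean surface, and derives
the downstream quantities an ecosystem analysis needs — ensemble
weights, regional light/temperature metrics, and thermal performance of
fish eggs and juveniles. It is aimed at marine ecologists and
climate-impact modellers working on seasonally ice-covered seas.

## The model

Per 1°×1° cell and month (six instantaneous evaluations, 4 h apart in
local solar time, on the 15th):

1. **Clear-sky spectra** (200–2700 nm, 10 nm bins): direct beam
   `I_d(λ) = E₀(λ) D T_R T_A T_W T_O T_U` (Rayleigh, aerosol, water
   vapour, ozone, mixed gases) plus scattered diffuse terms.
2. **Clouds**: the partly cloudy sky is a cloud-fraction-weighted
   average of the clear sky and a fully diffuse overcast sky; a
   Campbell–Norman diffuse fraction is available as a diagnostic.
3. **Bias factor** 1.17 on global irradiance (configurable).
4. **Albedo**: spectral open-water albedo (Fresnel over Cox–Munk wave
   slopes + whitecaps + chlorophyll-dependent water-leaving
   reflectance), blended by ice fraction with broadband ice/snow values:
   thick ice 0.52, snow-covered ice 0.65, a thin-ice ramp
   `f_h = min(atan(5h)/atan(2.5), 1)`, and a melt-pond reduction of up
   to 0.075 ramping in over air temperatures −1..0 °C.
5. **Attenuation**: snow `exp(−20 h_snow)` broadband, ice `exp(−k(λ) h_ice)`
   on 200–1000 nm, chlorophyll Beer–Lambert over a 0–5 m layer.
6. **Bands**: GHI, PAR (400–700 nm), UV (280–400 nm), UV-B (280–315 nm);
   PAR photons at 4.57 μmol s⁻¹ W⁻¹.

Ensemble members are weighted by performance and independence,
`w_i = exp(−D_i²/σ_D²) / (1 + Σ_{j≠i} exp(−S_ij²/σ_S²))` (normalized),
with D and S area-weighted RMSE distances of climatology, trend and
variability diagnostics. Thermal responses are unimodal curves pinned to
laboratory optima (e.g. polar cod eggs: peak 88% survival at 0.2 °C,
zero at the 4.5 °C lethal limit). A tested synthetic-forcing generator
emulates the seasonal cycles and scenario trends of all twelve input
variables, so the whole pipeline runs without external archives.

## Worked example

One June cell at 72°N with 60% ice cover, 0.9 m ice under 5 cm of snow
on 70% of it, 80% cloud, and a moderate bloom:

```r
library(cryolight)
f <- list(tas = -1.5, siconc = 0.6, sisnthick = 0.05, chl = 0.8,
          sithick = 0.9, sisnconc = 0.7, clt = 0.8, uas = 4, vas = 2,
          toz = 340, tos = 0.5, prw = 6)
bl <- simulate_cell_month(f, lat = 72, date = as.Date("2000-06-15"))
str(bl, digits.d = 3)
#> List of 10
#>  $ ghi_interface   : num 184
#>  $ par_interface   : num 73.8
#>  $ uv_interface    : num 9.67
#>  $ uvb_interface   : num 0.125
#>  $ ghi_water       : num 70.9
#>  $ par_water       : num 30.3
#>  $ uv_water        : num 3.8
#>  $ uvb_water       : num 0.0491
#>  $ par_water_layer : num 29.2
#>  $ albedo_broadband: num 0.405
```

Of 184 W m⁻² reaching the surface, 74 W m⁻² is visible (PAR); albedo
and ice/snow attenuation leave 30 W m⁻² of PAR in the water (29 W m⁻²
as the chlorophyll-attenuated 0–5 m layer mean) — far above the
0.1 W m⁻² (0.457 μmol photons m⁻² s⁻¹) visual-feeding threshold:

```r
par_to_photon_flux(bl$par_water)
#> [1] 138.2684
thermal_response(c(1, 3), "polar_cod", "egg")   # egg survival %, degC
#> [1] 86.05841 65.22705
```

Gridded runs use the same chain over a forcing set
(`run_rtm(forcings, rtm_config(...))`), with feature toggles for melt
ponds, wind, chlorophyll, the ocean-surface-albedo scheme and the snow
coefficient mirroring the model's sensitivity experiments. A thin CLI
(`inst/cli/cryolight`) wraps synthetic-forcing generation, gridded runs
and sensitivity comparisons.

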