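Package: cryolight
Title: Spectral Radiative Transfer and Light-Driven Ecosystem Metrics for
    Seasonally Ice-Covered Seas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts monthly climate-model forcings (clouds, ozone, water
    vapour, sea ice, snow, wind, chlorophyll-a, temperature) into spectrally
    resolved shortwave irradiance entering polar surface waters. Implements a
    simple clear-sky spectral solar model (200-2700 nm at 10 nm) with a cloud
    opacity adjustment, an ocean surface albedo scheme depending on solar
    zenith angle, wind and chlorophyll, sea-ice/snow/melt-pond albedo
    parameterizations, and spectral attenuation through snow, ice and
    chlorophyll-a. Downstream tools compute performance-and-independence
    ensemble weights, area-weighted regional metrics (rolling means, decadal
    monthly anomalies, threshold-duration statistics), and thermal performance
    curves for egg survival and juvenile growth of polar cod, Atlantic cod and
    walleye pollock. A synthetic-forcing generator emulates the seasonal
    cycles and scenario trends of the twelve required forcing variables so the
    full pipeline can run without external archives.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
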