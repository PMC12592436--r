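# Independent oracles implemented directly in the tests.

# Broadband clear-sky closed-form model (Bird-Hulstrom formulation):
# fully independent of the package's spectral path; used as the reference
# for broadband global irradiance.
oracle_broadband_ghi <- function(zdeg, o3_cm = 0.3, w_cm = 1,
                                 aod500 = 0.1, alpha = 1.14, rg = 0.06) {
  z <- zdeg * pi / 180; cz <- cos(z)
  m <- 1 / (cz + 0.15 * (93.885 - zdeg)^-1.253)
  tr <- exp(-0.0903 * m^0.84 * (1 + m - m^1.01))
  x0 <- o3_cm * m
  to <- 1 - 0.1611 * x0 * (1 + 139.48 * x0)^-0.3035 -
    0.002715 * x0 / (1 + 0.044 * x0 + 0.0003 * x0^2)
  tum <- exp(-0.0127 * m^0.26)
  xw <- w_cm * m
  tw <- 1 - 2.4959 * xw / ((1 + 79.034 * xw)^0.6828 + 6.385 * xw)
  beta <- aod500 * 0.5^alpha
  taua <- 0.2758 * beta * 0.38^-alpha + 0.35 * beta * 0.5^-alpha
  ta <- exp(-taua^0.873 * (1 + taua - taua^0.7088) * m^0.9108)
  taa <- 1 - 0.1 * (1 - m + m^1.06) * (1 - ta)
  tas <- ta / taa
  id <- 0.9662 * 1353 * tr * to * tum * tw * ta
  ias <- 0.79 * 1353 * cz * to * tum * tw * taa *
    (0.5 * (1 - tr) + 0.85 * (1 - tas)) / (1 - m + m^1.02)
  rs <- 0.0685 + 0.17 * (1 - tas)
  (id * cz + ias) / (1 - rg * rs)
}

# direct Fresnel reflectance for unpolarized light (hand formula)
oracle_fresnel <- function(theta_deg, n = 1.34) {
  if (theta_deg < 1e-9) return(((n - 1) / (n + 1))^2)
  ti <- theta_deg * pi / 180
  tt <- asin(sin(ti) / n)
  0.5 * ((sin(ti - tt) / sin(ti + tt))^2 + (tan(ti - tt) / tan(ti + tt))^2)
}
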