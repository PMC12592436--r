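test_that("sun below the horizon gives an all-zero spectrum", {
  cs <- clearsky_spectral(solar_geometry(95), toz = 300, prw = 10)
  expect_true(all(cs$dni == 0) && all(cs$dhi == 0))
  expect_error(clearsky_spectral(solar_geometry(30), toz = 0, prw = 10),
               "toz")
})

test_that("spectra are nonnegative and the direct beam shrinks with airmass", {
  dni_broad <- sapply(c(20, 40, 60, 75, 85), function(z) {
    cs <- clearsky_spectral(solar_geometry(z), toz = 300, prw = 10)
    expect_gte(min(cs$dni), 0)
    expect_gte(min(cs$dhi), 0)
    band_integrate(cs$dni, "ghi")
  })
  expect_true(all(diff(dni_broad) < 0))
})

test_that("ozone absorbs in the UV-B but leaves PAR nearly unchanged", {
  lo <- clearsky_spectral(solar_geometry(45), toz = 300, prw = 10)
  hi <- clearsky_spectral(solar_geometry(45), toz = 600, prw = 10)
  expect_lt(band_integrate(spectral_ghi(hi), "uvb"),
            band_integrate(spectral_ghi(lo), "uvb"))
  # doubling the column changes PAR by the small Chappuis-band absorption
  # (~2%), orders of magnitude less than the UV-B response
  par_change <- abs(band_integrate(spectral_ghi(hi), "par") /
                      band_integrate(spectral_ghi(lo), "par") - 1)
  uvb_change <- 1 - band_integrate(spectral_ghi(hi), "uvb") /
    band_integrate(spectral_ghi(lo), "uvb")
  expect_lt(par_change, 0.03)
  expect_gt(uvb_change, 10 * par_change)
  # strict monotonicity over a toz sweep
  uvb <- sapply(seq(250, 550, by = 50), function(o3)
    band_integrate(spectral_ghi(
      clearsky_spectral(solar_geometry(45), toz = o3, prw = 10)), "uvb"))
  expect_true(all(diff(uvb) < 0))
})

test_that("broadband global irradiance agrees with an independent closed-form model", {
  for (z in c(30, 60, 80)) {
    cs <- clearsky_spectral(solar_geometry(z), toz = 300, prw = 10)
    mine <- band_integrate(spectral_ghi(cs), "ghi")
    ref <- oracle_broadband_ghi(z, o3_cm = 0.3, w_cm = 1)
    expect_lt(abs(mine / ref - 1), 0.05)
  }
})

test_that("diffuse fraction has the overcast and clear limits and is monotone", {
  g <- solar_geometry(50)
  expect_equal(diffuse_fraction(1, g), 1)
  rho0 <- diffuse_fraction(0, g)
  m <- cryolight:::.airmass(50)
  tb <- 0.7^m
  expect_equal(rho0, 0.3 * (1 - tb) / (tb + 0.3 * (1 - tb)))
  rhos <- diffuse_fraction(seq(0, 1, by = 0.1), g)
  expect_true(all(diff(rhos) >= 0))
  expect_true(rhos[6] > rhos[1] && rhos[6] < rhos[11])
})

test_that("cloud opacity mixing has clear/overcast limits and decreases GHI", {
  g <- solar_geometry(50)
  clear <- clearsky_spectral(g, toz = 300, prw = 10)
  same <- apply_cloud_opacity(clear, 0, g)
  expect_identical(same$dni, clear$dni)
  expect_identical(same$dhi, clear$dhi)
  oc <- apply_cloud_opacity(clear, 1, g)
  expect_true(all(oc$dni == 0))
  expect_gt(band_integrate(oc$dhi, "ghi"), 0)
  ghis <- sapply(seq(0, 1, by = 0.1), function(cc)
    band_integrate(spectral_ghi(apply_cloud_opacity(clear, cc, g)), "ghi"))
  expect_true(all(diff(ghis) < 0))
})

test_that("ozone column conversion matches the trapezoidal pressure integral", {
  expect_equal(vmr_profile_to_dobson(ozone_profile(c(1000, 500, 0),
                                                   c(0, 0, 0))), 0)
  # uniform 1 ppm over 1000 hPa: 10 * R*T0/(g0*P0) * 1000 = 789.77 DU
  toz <- vmr_profile_to_dobson(ozone_profile(c(1000, 0), c(1, 1)))
  expect_equal(toz, 789.77, tolerance = 1e-4)
  # halving the pressure span halves the column
  expect_equal(vmr_profile_to_dobson(ozone_profile(c(500, 0), c(1, 1))),
               toz / 2)
  # linearity in the mixing ratio
  p <- c(1000, 700, 400, 100, 10)
  v <- c(0.02, 0.05, 1.2, 6.0, 2.0)
  expect_equal(vmr_profile_to_dobson(ozone_profile(p, 3 * v)),
               3 * vmr_profile_to_dobson(ozone_profile(p, v)))
  expect_error(ozone_profile(c(500, 1000), c(1, 1)), "decreasing")
  expect_error(ozone_profile(c(1000, 500), c(1, -1)), "nonnegative")
})
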