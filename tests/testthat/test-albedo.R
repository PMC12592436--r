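test_that("open-ocean albedo has the Fresnel limit and zenith monotonicity", {
  # overhead sun, calm sea, no chlorophyll: red wavelengths (negligible
  # water-leaving signal) sit at the Fresnel normal-incidence value
  osa0 <- osa_spectral(solar_geometry(0), wind = 0, chl = 0)
  red <- which(spectral_grid()$wl >= 700 & spectral_grid()$wl <= 900)
  expect_true(all(osa0$direct[red] > 0.02 & osa0$direct[red] < 0.03))
  expect_equal(mean(osa0$direct[red]), oracle_fresnel(0), tolerance = 0.005)

  a20 <- osa_spectral(solar_geometry(20), wind = 2, chl = 0.1)
  a80 <- osa_spectral(solar_geometry(80), wind = 2, chl = 0.1)
  expect_true(all(a80$direct > a20$direct))

  # grazing incidence reflects strongly, tracked by the Fresnel oracle
  # slope averaging over the calm-sea background roughness shifts the
  # grazing value slightly off the flat-surface Fresnel number
  calm80 <- osa_spectral(solar_geometry(80), wind = 0, chl = 0)
  expect_equal(mean(calm80$direct[red]), oracle_fresnel(80),
               tolerance = 0.05)
})

test_that("albedo stays within [0,1] across the admissible state space", {
  for (z in c(0, 30, 60, 85)) for (w in c(0, 7, 15)) for (ch in c(0, 1, 10)) {
    a <- osa_spectral(solar_geometry(z), wind = w, chl = ch)
    expect_true(all(a$direct >= 0 & a$direct <= 1))
    expect_true(all(a$diffuse >= 0 & a$diffuse <= 1))
  }
})

test_that("thin-ice ramp matches its arctangent definition", {
  expect_equal(thin_ice_blend_fh(0), 0)
  expect_equal(thin_ice_blend_fh(0.5), 1)
  expect_equal(thin_ice_blend_fh(5), 1)
  expect_equal(thin_ice_blend_fh(0.25), atan(1.25) / atan(2.5),
               tolerance = 1e-12)
  expect_true(all(diff(thin_ice_blend_fh(seq(0, 1, 0.05))) >= 0))
  expect_error(thin_ice_blend_fh(-0.1), "nonnegative")
})

test_that("dry ice albedo blends open water into the thick-ice value", {
  expect_equal(ice_albedo_dry(1, 0.07), 0.52)
  expect_equal(ice_albedo_dry(0, 0.07), 0.07)
  fh <- atan(0.5) / atan(2.5)
  expect_equal(ice_albedo_dry(0.1, 0.06), 0.06 * (1 - fh) + 0.52 * fh)
  expect_equal(ice_albedo_dry(0.1, 0.06), 0.2392, tolerance = 1e-4)
})

test_that("melt ponds reduce albedo on a linear ramp above -1 degC", {
  expect_equal(apply_melt_pond(0.52, -5), 0.52)
  expect_equal(apply_melt_pond(0.52, 2), 0.445)
  expect_equal(apply_melt_pond(0.52, -0.5), 0.4825)
  # continuity at the onset and saturation of the ramp
  expect_equal(apply_melt_pond(0.52, -1), 0.52)
  expect_equal(apply_melt_pond(0.52, 0), 0.445)
  expect_gte(apply_melt_pond(0.05, 10), 0)
})

test_that("composite cell albedo has the open-water, bare-ice and snow limits", {
  osa <- osa_spectral(solar_geometry(60), wind = 5, chl = 0.2)
  open <- composite_cell_albedo(surface_state(siconc = 0), osa)
  expect_identical(open$direct, osa$direct)
  expect_identical(open$diffuse, osa$diffuse)

  snow <- composite_cell_albedo(
    surface_state(siconc = 1, sisnconc = 1, sithick = 1, tas = -10), osa)
  expect_true(all(snow$direct == 0.65) && all(snow$diffuse == 0.65))

  bare <- composite_cell_albedo(
    surface_state(siconc = 1, sisnconc = 0, sithick = 1, tas = -10), osa)
  expect_true(all(bare$direct == 0.52))
})

test_that("composite albedo is monotone in ice and snow fractions (cold case)", {
  osa <- osa_spectral(solar_geometry(60), wind = 3, chl = 0.1)
  prev <- -Inf
  for (si in seq(0, 1, 0.25)) {
    a <- composite_cell_albedo(
      surface_state(siconc = si, sisnconc = 0, sithick = 2, tas = -10), osa)
    expect_gte(mean(a$direct), prev)
    prev <- mean(a$direct)
  }
  prev <- -Inf
  for (sn in seq(0, 1, 0.25)) {
    a <- composite_cell_albedo(
      surface_state(siconc = 1, sisnconc = sn, sithick = 2, tas = -10), osa)
    expect_gte(mean(a$direct), prev)
    prev <- mean(a$direct)
  }
})
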