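test_that("spherical cell areas follow the cosine law", {
  expect_equal(cell_area(90), 0)
  expect_equal(cell_area(60) / cell_area(0), 0.5)
  expect_equal(cell_area(60), 6371^2 * (pi / 180)^2 * 0.5,
               tolerance = 1e-9)
  expect_equal(round(cell_area(60)), 6182)
})

test_that("region masks are nonempty boxes at the documented center latitudes", {
  for (nm in c("bering_chukchi", "barents")) {
    rm <- region_mask(nm)
    expect_true(any(rm$mask))
    lats_in <- grid_1x1()$lat[rowSums(rm$mask) > 0]
    expect_equal(mean(range(lats_in)), rm$center_lat)
  }
})

test_that("area-weighted means use cosine-latitude weights", {
  time <- cryolight:::month_stamps(2000, 2000)[1]
  mk <- function(vals, lats) {
    v <- array(NA_real_, c(1, length(lats), 1))
    v[1, , 1] <- vals
    list(values = v, lat = lats, lon = 0, time = time)
  }
  m <- matrix(TRUE, 2, 1)
  expect_equal(area_weighted_mean(mk(c(4.2, 4.2), c(60, 60)), m), 4.2)
  expect_equal(area_weighted_mean(mk(c(0, 2), c(65, 65)), m), 1)
  # distinct latitudes: cos-weighted blend
  expect_equal(area_weighted_mean(mk(c(1, 0), c(60, 80)), m),
               cos(pi / 3) / (cos(pi / 3) + cos(80 * pi / 180)),
               tolerance = 1e-6)
  expect_equal(round(area_weighted_mean(mk(c(1, 0), c(60, 80)), m), 4),
               0.7422)
  expect_error(area_weighted_mean(mk(c(1, 0), c(60, 80)),
                                  matrix(FALSE, 2, 1)), "masked")
})

test_that("rolling means preserve constants and linear interiors", {
  expect_equal(rolling_mean(rep(2, 10)), rep(2, 10))
  lin <- rolling_mean(1:10, 5)
  expect_equal(lin[3:8], 3:8)
  step <- rolling_mean(c(0, 0, 0, 0, 1, 1, 1, 1), 3)
  expect_equal(step, c(0, 0, 0, 1/3, 2/3, 1, 1, 1))
})

test_that("decadal monthly anomalies vanish on the baseline and track shifts", {
  time <- cryolight:::month_stamps(1980, 2099)
  mo <- as.integer(format(time, "%m"))
  yr <- as.integer(format(time, "%Y"))
  base <- sin(2 * pi * mo / 12)
  tab0 <- decadal_monthly_anomaly(base, time)
  expect_true(all(abs(tab0[, -(1:2)]) < 1e-12))
  expect_equal(tab0$baseline, sin(2 * pi * (1:12) / 12))

  shifted <- base + ifelse(yr >= 2050, 1, 0)
  tab1 <- decadal_monthly_anomaly(shifted, time)
  expect_true(all(abs(tab1$d2050 - 1) < 1e-12))
  expect_true(all(abs(tab1$d2080 - 1) < 1e-12))
  expect_true(all(abs(tab1$d2000) < 1e-12))

  trended <- 0.02 * (yr + (mo - 0.5) / 12 - 1990)
  tab2 <- decadal_monthly_anomaly(trended, time)
  # baseline mean sits at 1990.5; the 2080s at 2085
  expect_equal(mean(tab2$d2080), 0.02 * (2085 - 1990.5), tolerance = 0.01)
  expect_error(decadal_monthly_anomaly(base[yr > 2050], time[yr > 2050]),
               "baseline")
})

test_that("threshold-duration counts interpolate fractional months", {
  time <- cryolight:::month_stamps(2000, 2000)
  all_above <- rep(5, 12)
  expect_equal(months_above_threshold(all_above, time, 1,
                                      "winter_spring")$months_above, 6)
  expect_equal(months_above_threshold(rep(0, 12), time, 1,
                                      "summer_fall")$months_above, 0)
  # crossing midway between the March and April centers: 0 below, then
  # above from April onwards within Jan-Jun -> 3 full months + 0.5
  v <- c(0, 0, 0, 2, 2, 2, 2, 2, 2, 2, 2, 2)
  got <- months_above_threshold(v, time, 1, "winter_spring")$months_above
  expect_equal(got, 3.5)
  # pointwise increase never decreases the count
  expect_gte(months_above_threshold(v + 1, time, 1,
                                    "winter_spring")$months_above, got)
  expect_warning(months_above_threshold(v[1:11], time[1:11], 1,
                                        "winter_spring"), "incomplete")
})

test_that("open-water and lit-area metrics have the limiting values", {
  time <- cryolight:::month_stamps(2000, 2000)[1:2]
  lats <- c(70, 71)
  si <- forcing_field("siconc",
                      array(c(1, 0), c(2, 2, 1)), lats, 0, time)
  m <- matrix(TRUE, 2, 1)
  ow <- open_water_fraction(si, m)
  expect_equal(ow$fraction, c(0, 1))
  # one of two longitudes open at every latitude: fraction one half
  si2 <- forcing_field("siconc", array(c(1, 1, 0.05, 0.05), c(1, 2, 2)),
                       lats, 0:1, time[1])
  expect_equal(open_water_fraction(si2, matrix(TRUE, 2, 2))$fraction, 0.5)

  lit <- list(values = array(c(0.05, 0.2, 0.2, 0.2), c(1, 2, 2)),
              lat = c(70, 70.0001), lon = 0:1, time = time[1])
  expect_equal(area_above_light(lit, matrix(TRUE, 2, 2))$fraction, 0.75,
               tolerance = 1e-6)
})
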