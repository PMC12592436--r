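test_that("forcing fields round-trip through the text format bit-exactly", {
  set.seed(42)
  time <- cryolight:::month_stamps(1995, 1996)
  vals <- array(rnorm(length(time) * 3 * 4), c(length(time), 3, 4))
  vals[5, 2, 3] <- NA  # missing cells must survive the round trip
  f <- forcing_field("tas", vals, 60:62, 10:13, time,
                     scenario = "historical", model_id = "SYN",
                     realization_id = "r9")
  path <- tempfile(fileext = ".txt")
  write_forcing(f, path)
  g <- read_forcing(path)
  expect_identical(g$values, f$values)
  expect_identical(g$variable_id, "tas")
  expect_identical(g$realization_id, "r9")
  expect_equal(g$time, f$time)
})

test_that("percent and kelvin units are normalized on construction", {
  time <- cryolight:::month_stamps(2000, 2000)
  pc <- array(runif(12 * 2 * 2, 0, 100), c(12, 2, 2))
  f <- forcing_field("siconc", pc, 60:61, 0:1, time, units = "%")
  expect_lte(max(f$values), 1)
  expect_identical(f$units, "1")
  kk <- array(273.15 + 5, c(12, 2, 2))
  g <- forcing_field("tas", kk, 60:61, 0:1, time, units = "K")
  expect_equal(unique(as.numeric(g$values)), 5)
})

test_that("malformed files and invalid fields are rejected", {
  path <- tempfile()
  writeLines(c("#cryolight-forcing 1", "variable_id: tos", "units: degC",
               "scenario: h", "model_id: m", "realization_id: r",
               "lat: 60", "lon: 0", "data:", "1"), path)
  expect_error(read_forcing(path), "time")
  expect_error(read_forcing(tempfile()), "not found")
  time <- cryolight:::month_stamps(2000, 2000)
  bad <- array(-0.5, c(12, 2, 2))
  expect_error(forcing_field("siconc", bad, 60:61, 0:1, time), "outside")
  # non-monthly time axis
  expect_error(forcing_field("tos", array(1, c(2, 1, 1)), 60, 0,
                             as.Date(c("2000-01-15", "2000-01-20"))),
               "monthly")
})

test_that("bilinear regridding reproduces constants and linear fields", {
  src_lat <- seq(58, 88, by = 2); src_lon <- seq(0, 358, by = 2)
  time <- cryolight:::month_stamps(2000, 2000)[1]
  const <- array(3.7, c(1, length(src_lat), length(src_lon)))
  f <- forcing_field("tos", const, src_lat, src_lon, time)
  out <- regrid_bilinear(f, grid_1x1())
  expect_equal(unique(as.numeric(out$values)), 3.7)

  # field linear in longitude is interpolated exactly (away from the wrap)
  lin <- array(rep(src_lon / 100, each = length(src_lat)),
               c(1, length(src_lat), length(src_lon)))
  dim(lin) <- c(1, length(src_lat), length(src_lon))
  fl <- forcing_field("tos", lin, src_lat, src_lon, time)
  outl <- regrid_bilinear(fl, grid_1x1())
  interior <- which(grid_1x1()$lon <= 357)
  expect_equal(as.numeric(outl$values[1, 5, interior]),
               grid_1x1()$lon[interior] / 100, tolerance = 1e-12)
})

test_that("checkerboard source yields 0.5 at midpoints and range is conserved", {
  src_lat <- seq(60, 70, by = 2); src_lon <- seq(0, 358, by = 2)
  time <- cryolight:::month_stamps(2000, 2000)[1]
  cb <- outer(seq_along(src_lat), seq_along(src_lon),
              function(i, j) (i + j) %% 2)
  vals <- array(cb, c(1, length(src_lat), length(src_lon)))
  vals <- aperm(array(cb, c(length(src_lat), length(src_lon), 1)), c(3, 1, 2))
  f <- forcing_field("tos", vals, src_lat, src_lon, time)
  tgt <- structure(list(lat = 61:69, lon = seq(1, 357, by = 2)),
                   class = "cryo_grid")
  out <- regrid_bilinear(f, tgt)
  expect_true(all(abs(out$values - 0.5) < 1e-12))
  expect_gte(min(out$values), min(vals))
  expect_lte(max(out$values), max(vals))
})

test_that("masked source cells renormalize weights over valid neighbours", {
  src_lat <- c(60, 62); src_lon <- c(0, 2)
  time <- cryolight:::month_stamps(2000, 2000)[1]
  vals <- array(c(1, NA, 3, 5), c(1, 2, 2))  # [1, lat, lon]
  f <- forcing_field("tos", vals, src_lat, src_lon, time)
  tgt <- structure(list(lat = 61, lon = 1), class = "cryo_grid")
  out <- regrid_bilinear(f, tgt)
  # equal weights over the three valid corners
  expect_equal(as.numeric(out$values), mean(c(1, 3, 5)))
  expect_error(regrid_bilinear(f, structure(list(lat = 60:90, lon = 1),
                                            class = "cryo_grid")),
               "latitude span")
})

test_that("historical + scenario splicing yields a continuous 1979-2100 series", {
  hist <- tiny_field("tos", 1, lats = 60:61, lons = 0:1,
                     years = c(1979, 2014), scenario = "historical")
  fut <- tiny_field("tos", 2, lats = 60:61, lons = 0:1,
                    years = c(2015, 2100), scenario = "ssp245")
  full <- concat_scenarios(hist, fut)
  expect_equal(length(full$time), 1464)  # 122 years x 12
  expect_identical(full$scenario, "ssp245")
  expect_true(all(diff(as.numeric(full$time)) > 27))

  gap <- tiny_field("tos", 2, lats = 60:61, lons = 0:1,
                    years = c(2016, 2020))
  expect_error(concat_scenarios(hist, gap), "splice")
  wrongvar <- tiny_field("tas", 2, lats = 60:61, lons = 0:1,
                         years = c(2015, 2020))
  expect_error(concat_scenarios(hist, wrongvar), "splice")
})
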