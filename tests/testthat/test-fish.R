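test_that("every thermal curve peaks exactly at its tabulated optimum", {
  tab <- species_params()
  tgrid <- seq(-3, 25, by = 0.001)
  for (i in seq_len(nrow(tab))) {
    p <- tab[i, ]
    r <- thermal_response(tgrid, params = p)
    expect_equal(max(r), p$peak, tolerance = 1e-6)
    expect_equal(tgrid[which.max(r)], p$t_opt, tolerance = 0.002)
    expect_equal(thermal_response(p$t_opt, params = p), p$peak)
    expect_true(all(r >= 0))
  }
})

test_that("responses are zero at and beyond the critical limits, continuously", {
  # polar cod eggs die at the 4.5 degC upper threshold
  expect_equal(thermal_response(4.5, "polar_cod", "egg"), 0)
  expect_equal(thermal_response(6, "polar_cod", "egg"), 0)
  expect_equal(thermal_response(-2, "polar_cod", "egg"), 0)
  expect_equal(thermal_response(0.2, "polar_cod", "egg"), 88)
  # juveniles tolerate -1..12 degC only
  expect_equal(thermal_response(13, "polar_cod", "juvenile"), 0)
  expect_equal(thermal_response(-1.5, "polar_cod", "juvenile"), 0)
  expect_gt(thermal_response(5, "polar_cod", "juvenile"), 0)
  # continuity: response shrinks smoothly approaching the limit
  near <- thermal_response(c(4.3, 4.45, 4.499, 4.4999), "polar_cod", "egg")
  expect_true(all(diff(near) < 0) && near[4] < 1)
  expect_error(thermal_response(1, "narwhal", "egg"), "unknown")
})

test_that("warming from the 85% baseline lowers polar cod egg survival as reported", {
  # find the warm-side baseline temperature where survival is 85%
  f <- function(t) thermal_response(t, "polar_cod", "egg") - 85
  t85 <- uniroot(f, c(0.2, 4.4))$root
  for (dt in c(1.2, 1.6, 2.0)) {
    hs <- hatch_success_delta(t85, dt)
    expect_equal(hs$baseline, 85, tolerance = 1e-6)
    expect_lt(hs$future, hs$baseline)
    expect_gt(hs$future, 55)
    expect_lt(hs$future, 80)
  }
  # cooling toward the optimum raises survival
  hs_cool <- hatch_success_delta(t85, -(t85 - 0.2))
  expect_gte(hs_cool$future, hs_cool$baseline)
  same <- hatch_success_delta(2, 0)
  expect_equal(same$baseline, same$future)
})

test_that("regional stage metrics area-average the curve correctly", {
  p <- species_params("polar_cod", "egg")
  time <- cryolight:::month_stamps(2000, 2000)
  lats <- c(70, 74)
  mk <- function(temps) {
    vals <- array(NA_real_, c(12, 2, 1))
    for (i in 1:2) vals[, i, 1] <- temps[i]
    forcing_field("tos", vals, lats, 0, time)
  }
  m <- matrix(TRUE, 2, 1)

  # uniform optimum temperature: metric equals the peak with zero spread
  opt <- seasonal_stage_metric(mk(c(0.2, 0.2)), "polar_cod", "egg", m)
  expect_equal(opt$value, 88)
  expect_equal(opt$hi - opt$lo, 0)

  # uniformly lethal temperatures: zero
  hot <- seasonal_stage_metric(mk(c(8, 8)), "polar_cod", "egg", m)
  expect_equal(hot$value, 0)

  # two cells at distinct temperatures: cosine-area-weighted blend
  two <- seasonal_stage_metric(mk(c(0.2, 2)), "polar_cod", "egg", m)
  w <- cos(lats * pi / 180)
  hand <- (w[1] * 88 + w[2] * thermal_response(2, "polar_cod", "egg")) /
    sum(w)
  expect_equal(two$value, hand, tolerance = 1e-9)
})
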