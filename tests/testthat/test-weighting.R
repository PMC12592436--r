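make_field <- function(fun, lats = 66:70, lons = 0:2,
                       years = c(2000, 2019)) {
  time <- cryolight:::month_stamps(years[1], years[2])
  yr <- as.numeric(format(time, "%Y")) +
    (as.numeric(format(time, "%m")) - 0.5) / 12
  vals <- array(NA_real_, c(length(time), length(lats), length(lons)))
  for (i in seq_along(lats)) for (j in seq_along(lons))
    vals[, i, j] <- fun(yr, lats[i], lons[j])
  forcing_field("tos", vals, lats, lons, time)
}

test_that("diagnostics recover climatology, trend and variability", {
  const <- make_field(function(t, la, lo) 3)
  d <- compute_diagnostics(const)
  expect_true(all(d$clim == 3))
  expect_true(all(abs(d$trend) < 1e-12))
  expect_true(all(abs(d$sd) < 1e-12))

  lin <- make_field(function(t, la, lo) 1 + 0.05 * (t - 2000))
  dl <- compute_diagnostics(lin)
  expect_equal(as.numeric(dl$trend), rep(0.05, 15), tolerance = 1e-9)
  expect_true(all(dl$sd < 1e-9))

  # seasonal sinusoid + trend: slope recovered within 1%
  mixed <- make_field(function(t, la, lo)
    2 + 0.03 * (t - 2000) + 1.5 * cos(2 * pi * t))
  dm <- compute_diagnostics(mixed)
  expect_true(all(abs(dm$trend / 0.03 - 1) < 0.01))
  expect_true(all(dm$sd > 0.5))  # detrended sd keeps the seasonal signal

  short <- make_field(function(t, la, lo) t - 2000, years = c(2000, 2004))
  expect_error(compute_diagnostics(short), "10 years")
})

test_that("distances vanish for identical fields and match hand arithmetic", {
  obs <- compute_diagnostics(make_field(function(t, la, lo) 1 + 0.01 * t))
  m1 <- obs
  dist <- compute_distances(list(a = m1, b = m1), obs)
  expect_equal(unname(dist$D), c(0, 0))
  expect_equal(dist$S["a", "b"], 0)

  # two-cell hand computation of the area-weighted climatology RMSE
  lat2 <- c(66, 70)
  t1 <- cryolight:::month_stamps(2000, 2019)
  mk <- function(v1, v2) {
    vals <- array(NA_real_, c(length(t1), 2, 1))
    vals[, 1, 1] <- v1; vals[, 2, 1] <- v2
    compute_diagnostics(forcing_field("tos", vals, lat2, 0, t1))
  }
  obs2 <- mk(0, 0)
  mod2 <- mk(1, 3)
  w <- cos(lat2 * pi / 180)
  hand <- sqrt((w[1] * 1 + w[2] * 9) / sum(w))
  expect_equal(cryolight:::.aw_rmse(mod2$clim, obs2$clim, lat2), hand)
})

test_that("weights reproduce the closed-form limits", {
  # single perfect model
  expect_equal(compute_weights(0, matrix(0, 1, 1), 1, 1)$w, 1)
  # M identical models: raw weight 1/M each, normalized 1/M
  m <- 4
  wts <- compute_weights(rep(0, m), matrix(0, m, m), 1, 1)
  expect_equal(wts$raw, rep(1 / m, m))
  expect_equal(wts$w, rep(1 / m, m))
  # one model at D = sigma_D with no neighbours: raw weight e^-1
  solo <- compute_weights(2, matrix(0, 1, 1), sigma_d = 2, sigma_s = 1)
  expect_equal(solo$raw, exp(-1))
  expect_error(compute_weights(c(1, 1), matrix(0, 2, 2), sigma_d = -1,
                               sigma_s = 1), "positive")
})

test_that("duplicating a model is penalized by the independence term", {
  s_unique <- matrix(5, 3, 3); diag(s_unique) <- 0
  w3 <- compute_weights(c(0.5, 0.5, 0.5), s_unique, sigma_d = 1, sigma_s = 1)
  # add a duplicate of model 1 (distance 0 to it)
  s_dup <- matrix(5, 4, 4); diag(s_dup) <- 0
  s_dup[1, 4] <- s_dup[4, 1] <- 0
  w4 <- compute_weights(c(0.5, 0.5, 0.5, 0.5), s_dup, sigma_d = 1,
                        sigma_s = 1)
  expect_lt(w4$raw[1], w3$raw[1])
  expect_lt(w4$w[1], w3$w[1])
})

test_that("weighted ensemble means blend fields correctly and stay bounded", {
  a <- array(1, c(2, 2, 2)); b <- array(3, c(2, 2, 2))
  expect_equal(weighted_ensemble_mean(list(a, b), c(0.5, 0.5)),
               array(2, c(2, 2, 2)))
  expect_equal(weighted_ensemble_mean(list(a, b), c(1, 0)), a)
  blend <- weighted_ensemble_mean(list(a, b), c(0.25, 0.75))
  expect_equal(unique(as.numeric(blend)), 2.5)
  expect_true(all(blend >= pmin(a, b) & blend <= pmax(a, b)))
  expect_error(weighted_ensemble_mean(list(a, b), c(0.5, 0.4)), "sum to 1")
  expect_error(weighted_ensemble_mean(list(a), c(0.5, 0.5)), "mismatch")
})
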