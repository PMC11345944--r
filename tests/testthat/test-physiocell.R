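test_that("flow program interpolates the ramp and honours refill pulses", {
  sc <- default_scenario(3)  # GET 30 min: refill pulse at 30
  expect_equal(flow_rate(0, sc$flow), 50)
  expect_equal(flow_rate(14, sc$flow), 8)
  expect_equal(flow_rate(25, sc$flow), 8)
  expect_equal(flow_rate(7, sc$flow), 29)  # linear between 50 and 8
  expect_equal(flow_rate(30.1, sc$flow), 110)      # inside the 18 s window
  expect_equal(flow_rate(30.4, sc$flow), 8)        # after the window
  expect_error(flow_program(breakpoints = data.frame(time_min = c(5, 1),
                                                     flow_ml_min = c(1, 1))),
               "increasing")
})

test_that("release fraction follows the (double) Weibull closed form", {
  p <- release_params("weibull", tlag = 10, tau = 20, b = 1.4)
  expect_equal(release_fraction(10, p), 0)
  expect_equal(release_fraction(5, p), 0)
  expect_equal(release_fraction(30, p), 1 - exp(-1))  # t - tlag = tau
  expect_equal(release_fraction(1e5, p), 1, tolerance = 1e-12)
  tt <- seq(0, 200, by = 0.5)
  expect_true(all(diff(release_fraction(tt, p)) >= 0))

  dw <- release_params("double_weibull", tlag = 5, tau = 10, b = 1.2,
                       tau2 = 100, b2 = 2, w = 0.3)
  w1 <- 1 - exp(-((50 - 5) / 10)^1.2)
  w2 <- 1 - exp(-((50 - 5) / 100)^2)
  expect_equal(release_fraction(50, dw), 0.3 * w1 + 0.7 * w2)
  expect_true(all(diff(release_fraction(tt, dw)) >= 0))

  expect_error(release_params("weibull", tau = -1, b = 1), "positive")
  expect_error(release_params("double_weibull", tau = 1, b = 1,
                              tau2 = 2, b2 = 2, w = 1.4), "0, 1")
})

test_that("the modified Noyes-Whitney rate has the z-factor form", {
  p <- release_params("weibull", tau = 10, b = 1, z = 1.08, cs = 27,
                      x0 = 100)
  # full undissolved dose in the stress cell volume
  expect_equal(nw_rate(100, 0, 34, p), 1.08 * 100 * 27)
  expect_equal(nw_rate(0, 10, 34, p), 0)
  expect_equal(nw_rate(50, 27 * 34, 34, p), 0)  # at saturation
  expect_equal(nw_rate(8, 0, 500, p),
               1.08 * 100^(1 / 3) * 8^(2 / 3) * 27)
  expect_error(nw_rate(10, 0, -1, p), "positive")
})

test_that("the apparatus twin conserves mass and reproduces program shapes", {
  for (g in c(1, 3, 6)) {
    prof <- simulate_invitro(default_scenario(g), default_release_params(g))
    st <- attr(prof, "states")
    expect_lt(max(abs(rowSums(st[, -1]) - 100)), 1e-4)  # 1e-6 of the dose
    expect_true(all(diff(prof$dissolved_mg) > -1e-9))   # no precipitation
  }

  # early housekeeper wave: nearly complete dissolution by 30 min
  g1 <- simulate_invitro(default_scenario(1), default_release_params(1))
  expect_gte(g1$dissolved_pct[g1$times == 30], 95)

  # late GET with slow spontaneous release: pre-GET plateau below the
  # post-GET level
  slow <- release_params("weibull", tlag = 10, tau = 120, b = 1.3)
  g6 <- simulate_invitro(default_scenario(6), slow)
  expect_lt(g6$dissolved_pct[g6$times == 88], 0.9 * max(g6$dissolved_pct))

  # instant release with a very large z dissolves almost immediately
  fast <- release_params("weibull", tlag = 0, tau = 0.5, b = 1, z = 50)
  gf <- simulate_invitro(default_scenario(4), fast)
  expect_gte(gf$dissolved_pct[gf$times == 6], 99)
})

test_that("tightening the integrator tolerance does not change the profile", {
  sc <- default_scenario(3)
  p <- default_release_params(3)
  a <- simulate_invitro(sc, p)
  b <- simulate_invitro(sc, p, rtol = 1e-10, atol = 1e-10)
  expect_equal(a$dissolved_mg, b$dissolved_mg, tolerance = 1e-6)
})

test_that("release fitting recovers generating parameters before the GET", {
  # single Weibull, informative window (GET 60 min)
  sc <- default_scenario(5)
  p <- default_release_params(5)
  prof <- simulate_invitro(sc, p)
  fit <- fit_release(prof, sc, kind = "weibull")
  expect_true(fit$fit$converged)
  expect_equal(fit$tau, p$tau, tolerance = 1e-3)
  expect_equal(fit$b, p$b, tolerance = 1e-3)
  expect_equal(fit$tlag, p$tlag, tolerance = 0.05)

  # double Weibull with an inflection is detected and recovered
  sc3 <- default_scenario(3)
  p3 <- default_release_params(3)
  prof3 <- simulate_invitro(sc3, p3)
  fit3 <- fit_release(prof3, sc3, kind = "double_weibull")
  expect_equal(fit3$tau, p3$tau, tolerance = 0.02)
  expect_equal(fit3$w, p3$w, tolerance = 0.02)

  # profile entirely after the GET cannot be fitted
  late <- invitro_profile(seq(32, 50, by = 2),
                          seq(60, 100, length.out = 10))
  expect_error(fit_release(late, sc3), "pre-GET")
})

test_that("z fitting from the post-GET burst is exact and scales", {
  sc <- default_scenario(1)
  p <- default_release_params(1)
  prof <- simulate_invitro(sc, p)
  z1 <- fit_z(prof, sc, p)
  expect_equal(as.numeric(z1), 1.08, tolerance = 1e-3)

  p2 <- p
  p2$z <- 2.16
  z2 <- fit_z(simulate_invitro(sc, p2), sc, p)
  expect_equal(as.numeric(z2), 2.16, tolerance = 1e-3)

  short <- invitro_profile(c(0, 2, 14, 16), c(0, 1, 2, 50))
  expect_error(fit_z(short, sc, p, n_points = 3), "fewer than")
  expect_error(fit_z(prof, sc, p, n_points = 2), "at least 3")
})
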