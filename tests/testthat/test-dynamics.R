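test_that("light competition attenuates growth as the canopy fills", {
  p <- tiny_params(m = 2)
  # a group alone in the terrace grows at the full rate Lambda0
  expect_equal(light_factor(c(5, 0), i = 1, params = p), 0.3)
  # two equal groups of 10 with B_R = 20
  expect_equal(light_factor(c(10, 10), i = 1, params = p), 0.3 * (1 - 10 / 40))
  # a rare group under a massive canopy grows hardly at all
  expect_lt(light_factor(c(1e-6, 1e5), i = 1, params = p), 1e-4)
})

test_that("bare soil is invariant and uptake is half-saturated at W = 60", {
  p <- tiny_params(m = 3, n = 2)
  st <- riverbed_state(p, B = 0, W = 10, H = 1)
  d <- rhs(st, P_now = 50, params = p)
  expect_true(all(d$dB == 0))
  # per-capita growth at the half-saturation soil-water density:
  # Lambda0 * 60/2 - M = 8.9 per year in the rare-group limit
  st2 <- riverbed_state(p, B = 1e-10, W = 60, H = 0)
  d2 <- rhs(st2, P_now = 0, params = p)
  expect_equal(d2$dB[1, 1] / st2$B[1, 1], 0.3 * 30 - 0.1, tolerance = 1e-6)
})

test_that("surface water decays exponentially at rate I + D without rain", {
  p <- tiny_params(m = 2, n = 1)
  st <- riverbed_state(p, B = 0, W = 0, H = 7)
  d <- rhs(st, P_now = 0, params = p)
  expect_equal(d$dH, -(p$I + p$D) * 7)
  # one RK4 step reproduces the exponential to local order dt^5
  dt <- 0.01
  s1 <- rk4_step(st, dt, const_series(0, 10), p)
  exact <- 7 * exp(-(p$I + p$D) * dt)
  expect_lt(abs(s1$H - exact), 10 * ((p$I + p$D) * dt)^5 / 120 * 7)
  # halving the step shrinks the (global) error ~16x: fourth order
  two <- rk4_step(rk4_step(st, dt / 2, const_series(0, 10), p),
                  dt / 2, const_series(0, 10), p)
  ratio <- abs(s1$H - exact) / abs(two$H - exact)
  expect_gt(ratio, 12); expect_lt(ratio, 24)
})

test_that("the compiled integrator matches the pure-R stepper", {
  p <- tiny_params(m = 5, n = 2)
  st <- riverbed_state(p)
  ser <- const_series(200, 2)
  stR <- st
  for (i in 1:365) stR <- rk4_step(stR, 1 / 365, ser, p)
  rc <- simulate(st, ser, p, years = 1, dt = 1 / 365)
  expect_equal(rc$state$B, stR$B, tolerance = 1e-10)
  expect_equal(rc$state$W, stR$W, tolerance = 1e-10)
  expect_equal(rc$state$H, stR$H, tolerance = 1e-10)
  # and with the discontinuous square wave over a short window
  reg <- regime_from_MAP(k = 1, MAP = 100)
  stR2 <- riverbed_state(p, W = 5)
  for (i in 1:1460) stR2 <- rk4_step(stR2, 1 / 1460, reg, p)
  rc2 <- simulate(riverbed_state(p, W = 5), reg, p, years = 1)
  expect_equal(rc2$state$B, stR2$B, tolerance = 1e-6)
  expect_equal(rc2$state$W, stR2$W, tolerance = 1e-6)
})

test_that("an independent deSolve integration reproduces a single terrace", {
  expect_true(requireNamespace("deSolve", quietly = TRUE))
  p <- tiny_params(m = 3, n = 1)
  st <- riverbed_state(p, B = 0.05, W = 2, H = 1)
  f <- function(t, y, parms) {
    # bypass the validating constructor: trial steps may go slightly negative
    s <- structure(list(B = matrix(y[1:3], 3, 1), W = y[4], H = y[5], t = t),
                   class = "riverbed_state")
    d <- rhs(s, P_now = 150, params = p)
    list(c(d$dB, d$dW, d$dH))
  }
  out <- deSolve::ode(y = c(st$B, st$W, st$H), times = c(0, 1), func = f,
                      parms = NULL, method = "ode45", atol = 1e-10,
                      rtol = 1e-10)
  rc <- simulate(st, const_series(150, 2), p, years = 1, dt = 1 / 1460)
  expect_equal(as.numeric(rc$state$B), as.numeric(out[2, 2:4]),
               tolerance = 1e-7)
  expect_equal(rc$state$W, as.numeric(out[2, 5]), tolerance = 1e-7)
  expect_equal(rc$state$H, as.numeric(out[2, 6]), tolerance = 1e-7)
})

test_that("the fixed-step scheme is fourth-order on the full system", {
  p <- tiny_params(m = 4, n = 2)
  st <- riverbed_state(p, B = 0.1, W = 1)
  ser <- const_series(300, 2)
  run <- function(spy) simulate(st, ser, p, years = 1, dt = 1 / spy)$state
  x1 <- run(365); x2 <- run(730); x4 <- run(1460)
  d1 <- max(abs(x1$B - x2$B), abs(x1$W - x2$W), abs(x1$H - x2$H))
  d2 <- max(abs(x2$B - x4$B), abs(x2$W - x4$W), abs(x2$H - x4$H))
  expect_gt(d1 / d2, 10)
  expect_lt(d1 / d2, 30)
})

test_that("zero state under zero forcing is a fixed point", {
  p <- tiny_params()
  st <- riverbed_state(p, B = 0, W = 0, H = 0)
  r <- simulate(st, regime_from_MAP(k = 1, MAP = 0), p, years = 2)
  expect_equal(r$state$B, st$B)
  expect_equal(r$state$W, st$W)
  expect_equal(r$state$H, st$H)
})

test_that("without rain all biomass decays toward zero", {
  p <- tiny_params(m = 5, n = 2)
  st <- riverbed_state(p, B = 1, W = 0, H = 0)
  # dry soil reduces the biomass equation to pure loss dB = -M B
  r <- simulate(st, regime_from_MAP(k = 1, MAP = 0), p, years = 60)
  expect_true(all(diff(r$B_total) < 0))
  expect_equal(r$B_total[60], sum(st$B) * exp(-0.1 * 60), tolerance = 1e-8)
})

test_that("states stay non-negative and clamping is negligible", {
  p <- tiny_params(m = 10, n = 3)
  r <- simulate(riverbed_state(p), regime_from_MAP(k = 6, MAP = 100), p,
                years = 25)
  expect_true(all(r$state$B >= 0) && all(r$state$W >= 0) &&
              all(r$state$H >= 0))
  expect_true(all(r$clamped < 1e-6 * pmax(r$B_total, 1)))
})

test_that("uncoupled identical terraces stay bitwise identical", {
  pool <- tiny_pool(m = 8)
  p <- model_params(pool = pool, n_terraces = 4, D = 0, alpha1 = 0)
  r <- simulate(riverbed_state(p), regime_from_MAP(k = 6, MAP = 100), p,
                years = 10)
  for (j in 2:4) expect_identical(r$state$B[, j], r$state$B[, 1])
  expect_identical(r$state$W, rep(r$state$W[1], 4))
})

test_that("the biomass-free water budget closes over a settled year", {
  pool <- tiny_pool(m = 2)
  p <- model_params(pool = pool, n_terraces = 2)
  reg <- regime_from_MAP(k = 1, MAP = 100)
  st <- simulate(riverbed_state(p, B = 0), reg, p, years = 30)$state
  # accumulate fluxes over one more year with the R stepper (trapezoid)
  dt <- 1 / 1460
  Pf <- function(t) precip_at(t, reg)
  infil <- outflow <- rain <- 0
  s <- st
  for (i in 1:1460) {
    t0 <- s$t
    in0 <- p$I * sum(s$H); out0 <- p$D * s$H[1]
    P0 <- Pf(t0)
    rain0 <- p$n_terraces * P0 + alpha_runoff(P0 / 365) * P0
    s <- rk4_step(s, dt, reg, p)
    P1 <- Pf(s$t)
    infil <- infil + dt * (in0 + p$I * sum(s$H)) / 2
    outflow <- outflow + dt * (out0 + p$D * s$H[1]) / 2
    rain <- rain + dt * (rain0 + p$n_terraces * P1 +
                           alpha_runoff(P1 / 365) * P1) / 2
  }
  dH <- sum(s$H) - sum(st$H)
  expect_equal(infil + outflow + dH, rain, tolerance = 0.01)
})

test_that("steady states are annually periodic and inoculum-independent", {
  p <- tiny_params(m = 5, n = 2)
  reg <- regime_from_MAP(k = 6, MAP = 100)
  ss <- run_to_steady_state(riverbed_state(p), reg, p, tol = 1e-7,
                            max_years = 400)
  expect_true(ss$converged)
  again <- simulate(ss$state, reg, p, years = 1)
  expect_lt(max(abs(again$state$B - ss$state$B)), 1e-6 * max(ss$state$B))
  ss2 <- run_to_steady_state(riverbed_state(p, B = 0.04), reg, p,
                             tol = 1e-7, max_years = 400)
  expect_equal(sum(ss2$state$B), sum(ss$state$B), tolerance = 1e-4)
  # an empty riverbed under zero rain converges immediately
  ss0 <- run_to_steady_state(riverbed_state(p, B = 0),
                             regime_from_MAP(k = 1, MAP = 0), p,
                             max_years = 5)
  expect_true(ss0$converged)
  expect_equal(ss0$years, 1)
})

test_that("structural errors are caught", {
  p <- tiny_params(m = 5, n = 2)
  st <- riverbed_state(p)
  expect_error(rhs(st, P_now = -1, params = p), ">= 0")
  p2 <- tiny_params(m = 4, n = 2)
  expect_error(rhs(st, P_now = 0, params = p2), "dimensions")
  expect_error(riverbed_state(p, B = -0.1), ">= 0")
  expect_error(simulate(st, const_series(100, 1), p, years = 5), "horizon")
})
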