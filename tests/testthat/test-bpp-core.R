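# Forward BPP model: correlation times, rates, T1, and the T1 minimum.
# Expected numbers were frozen from direct high-precision evaluation of the
# Arrhenius and BPP expressions and from a grid+bisection scan for minima.

test_that("correlation_time follows the Arrhenius law", {
  cfg <- spectrometer_config()
  # Ea = 0 forces tau = tau0 at any temperature.
  expect_identical(correlation_time(motion(4.45e-12, 0, 0.1), 100, cfg),
                   4.45e-12)
  expect_equal(correlation_time(motion(4.45e-12, 12.77, 0.036), 300, cfg),
               7.4433957044e-10, tolerance = 1e-9)
  expect_equal(correlation_time(motion(2.12e-14, 19.55, 0.110), 194, cfg),
               3.8912102098e-09, tolerance = 1e-9)
  # Strictly decreasing in temperature when Ea > 0.
  m <- motion(1e-13, 15, 0.1)
  taus <- correlation_time(m, seq(80, 300, by = 20), cfg)
  expect_true(all(diff(taus) < 0))
  expect_error(correlation_time(m, -5), "positive")
  expect_error(correlation_time(m, 0), "positive")
})

test_that("very low temperatures cap the correlation time with a flag", {
  tau <- correlation_time(motion(1e-10, 55, 0.1), 2)
  expect_equal(as.numeric(tau), 1e3)
  expect_true(isTRUE(attr(tau, "capped")))
})

test_that("motion_rate matches the BPP expression and its limits", {
  cfg <- spectrometer_config()
  expect_identical(motion_rate(motion(1e-12, 10, 0), 100, cfg), 0)
  expect_equal(motion_rate(motion(2.12e-14, 19.55, 0.110), 194, cfg),
               0.4761675243, tolerance = 1e-8)
  expect_true(all(motion_rate(motion(1e-13, 20, 0.05),
                              seq(80, 300, by = 10), cfg) >= 0))
  # Extreme narrowing: w0*tau << 1 gives rate ~ (10/3) gamma^2 dM2 tau.
  m <- motion(1e-14, 1, 0.05)
  T_hot <- 300
  tau <- as.numeric(correlation_time(m, T_hot, cfg))
  expect_lt(cfg$omega0 * tau, 1e-3)
  expect_equal(motion_rate(m, T_hot, cfg),
               (10 / 3) * cfg$gamma^2 * m$dm2 * tau, tolerance = 1e-5)
})

test_that("total rate is additive over motions and T1 is its reciprocal", {
  cfg <- spectrometer_config()
  m <- motion(1e-13, 15, 0.08)
  two <- relaxation_model(list(m, m), cfg)
  one <- relaxation_model(list(m), cfg)
  expect_equal(total_rate(two, 150), 2 * total_rate(one, 150))
  # Reference three-motion magnolol model at 194 K vs brute-force sum.
  mag0 <- mag0_model()
  expect_equal(t1(mag0, 194), 1.740458793929, tolerance = 1e-9)
  rates <- vapply(mag0$motions, motion_rate, numeric(1),
                  temperature = 194, config = cfg)
  expect_equal(total_rate(mag0, 194), sum(rates), tolerance = 1e-12)
  # Positivity across the full range.
  expect_true(all(t1(mag0, seq(80, 300, length.out = 50)) > 0))
  empty <- relaxation_model(list(), cfg)
  expect_error(total_rate(empty, 100), "no motions")
})

test_that("the T1 minimum sits at w0 tau = 0.6158 and moves with frequency", {
  # Dense-scan oracle: the scan minimum and the solver agree.
  m <- motion(2.12e-14, 19.55, 0.110)
  res <- t1_minimum(m)
  expect_equal(res$temperature, 193.881, tolerance = 1e-3)
  cfg <- spectrometer_config()
  x <- cfg$omega0 * as.numeric(correlation_time(m, res$temperature, cfg))
  expect_equal(x, 0.6158, tolerance = 1e-3 / 0.6158)
  grid_T <- seq(120, 280, length.out = 20001)
  t1s <- t1(relaxation_model(list(m), cfg), grid_T)
  expect_equal(grid_T[which.min(t1s)], res$temperature, tolerance = 1e-3)
  expect_equal(min(t1s), res$t1_min, tolerance = 1e-6)

  hon1 <- t1_minimum(motion(9.99e-11, 8.40, 0.024))
  expect_equal(hon1$temperature, 275.302, tolerance = 1e-3)

  # Doubling w0 shifts the minimum to higher temperature.
  res2 <- t1_minimum(m, spectrometer_config(50))
  expect_gt(res2$temperature, res$temperature)
  # tau0 already above the tau at the minimum: solution beyond 1e4 K.
  expect_warning(t1_minimum(motion(2e-9, 60, 0.1)), "outside")
})

test_that("asymptotic log-T1 slopes approach +/- Ea/R", {
  cfg <- spectrometer_config()
  m <- motion(1e-13, 20, 0.1)
  mdl <- relaxation_model(list(m), cfg)
  slope <- function(Ta, Tb) {
    (log(t1(mdl, Tb)) - log(t1(mdl, Ta))) / (1 / Tb - 1 / Ta)
  }
  ea_R <- m$ea * 1000 / cfg$gas_constant
  # Extreme narrowing branch (hot): d ln T1 / d(1/T) -> -Ea/R.
  expect_equal(slope(2000, 2001), -ea_R, tolerance = 0.01)
  # Slow-motion branch (cold, w0 tau >> 1): -> +Ea/R.
  expect_equal(slope(100, 100.05), ea_R, tolerance = 0.01)
})

test_that("frequency dependence: w0^2 scaling cold, none hot", {
  m <- motion(1e-13, 20, 0.1)
  f1 <- spectrometer_config(25); f2 <- spectrometer_config(50)
  m1 <- relaxation_model(list(m), f1); m2 <- relaxation_model(list(m), f2)
  # Slow motion (w0 tau >> 1): T1 scales as w0^2.
  expect_gt(f1$omega0 * as.numeric(correlation_time(m, 80, f1)), 1e3)
  expect_equal(t1(m2, 80) / t1(m1, 80), 4, tolerance = 1e-3)
  # Extreme narrowing: frequency-independent.
  expect_lt(f2$omega0 * as.numeric(correlation_time(m, 2000, f2)), 1e-3)
  expect_equal(t1(m2, 2000) / t1(m1, 2000), 1, tolerance = 1e-3)
})

test_that("constructors validate their invariants", {
  expect_error(motion(-1e-12, 10, 0.1), "tau0")
  expect_error(motion(1e-12, -1, 0.1), "ea")
  expect_error(motion(1e-12, 10, -0.1), "dm2")
  expect_error(spectrometer_config(0), "positive")
  cfg <- spectrometer_config(25)
  expect_equal(cfg$omega0, 2 * pi * 25e6, tolerance = 1e-12)
  expect_error(relaxation_model(list(1, 2)), "motion")
})
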