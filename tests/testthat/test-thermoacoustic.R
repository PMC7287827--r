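med <- acoustic_medium()
gpulse <- pulse_profile(10e-6, "gaussian")

test_that("a single voxel reproduces the closed-form point source", {
  g <- dose_grid(array(0, dim = c(3, 3, 3)), origin = c(-1, -1, -1), spacing = 1)
  g$values[2, 2, 2] <- 800 # J/m^3 at the origin
  obs <- c(0, 0, 25)
  tr <- thermoacoustic_pressure(g, obs, med, gpulse, dt = 2e-8)
  oracle <- point_source_oracle(tr$t, 800 * 1e-9, 25, med, gpulse)
  expect_lt(rms(tr$p - oracle) / max(abs(oracle)), 0.01)
})

test_that("multi-voxel traces equal the superposition of point sources", {
  g <- random_grid(n = 3, seed = 42)
  obs <- c(1, 1, 30) # far enough that no voxel is subdivided
  tr <- thermoacoustic_pressure(g, obs, med, gpulse, dt = 2e-8)
  oracle <- superposition_oracle(tr$t, g, obs, med, gpulse)
  expect_lt(rms(tr$p - oracle) / max(abs(oracle)), 0.01)
})

test_that("zero dose gives an identically zero trace", {
  g <- dose_grid(array(0, dim = c(2, 2, 2)))
  tr <- thermoacoustic_pressure(g, c(0, 0, 10), med, gpulse)
  expect_true(all(tr$p == 0))
})

test_that("amplitude is exactly linear in deposited energy", {
  g <- random_grid(n = 3, seed = 1)
  g2 <- g
  g2$values <- 2 * g$values
  p1 <- max(abs(thermoacoustic_pressure(g, c(0, 0, 20), med, gpulse)$p))
  p2 <- max(abs(thermoacoustic_pressure(g2, c(0, 0, 20), med, gpulse)$p))
  expect_equal(p2 / p1, 2, tolerance = 1e-12)
})

test_that("traces are bipolar (zero time integral) and causal", {
  g <- random_grid(n = 3, seed = 3)
  obs <- c(0, 0, 40)
  tr <- thermoacoustic_pressure(g, obs, med, gpulse, dt = 2e-8)
  # bipolarity: the trace is a second derivative of a smooth kernel
  expect_lt(abs(sum(tr$p) * tr$dt),
            1e-3 * max(abs(tr$p)) * (max(tr$t) - min(tr$t)))
  # retarded-time causality
  dmin <- 38 # nearest voxel is at least 38 mm away (grid spans z in [0, 2])
  before <- tr$t < dmin * 1e-3 / med$cs - gpulse$duration
  expect_lt(max(abs(tr$p[before])), 1e-12 * max(abs(tr$p)))
})

test_that("too coarse a sampling step is refused with the bound", {
  g <- random_grid(n = 2)
  expect_error(thermoacoustic_pressure(g, c(0, 0, 10), med, gpulse, dt = 1e-3),
               "min\\(spacing\\)/cs")
})

test_that("attenuated_amplitude matches its closed form", {
  expect_equal(attenuated_amplitude(2.92, 2, 2), 2.92)
  # pure spherical spreading when absorption is off
  expect_equal(attenuated_amplitude(1, 5, 50, alpha_atten = 0), 0.1)
  # the printed propagation: 2.92 Pa at 2 mm -> 20 mm at 0.95 Np/m
  expect_equal(attenuated_amplitude(2.92, 2, 20, 0.95),
               2.92 * (2 / 20) * exp(-0.95 * 0.018), tolerance = 1e-12)
  expect_equal(attenuated_amplitude(2.92, 2, 20, 0.95), 0.287, tolerance = 1e-2)
  expect_error(attenuated_amplitude(1, 10, 5), "back-propagation")
})

test_that("pressure-distance table is strictly decreasing", {
  expect_equal(max_pressure_vs_distance(2.92, 2, 2)$pressure_Pa, 2.92)
  tab <- max_pressure_vs_distance(2.92, 2, seq(5, 40, by = 5), 0.95)
  expect_equal(nrow(tab), 8)
  expect_true(all(diff(tab$pressure_Pa) < 0))
  # spreading alone gives a factor 8 from 5 to 40 mm; absorption adds more
  expect_lt(tab$pressure_Pa[8], tab$pressure_Pa[1] / 8)
  expect_error(max_pressure_vs_distance(1, 2, c(10, 5)), "sorted")
})

test_that("central_frequency recovers known spectra", {
  dt <- 1e-7
  t <- (0:2047) * dt
  # pure sinusoid at 250 kHz
  tr <- pressure_trace(t, sin(2 * pi * 250e3 * t))
  expect_equal(central_frequency(tr)$f_central, 250e3, tolerance = 0.05)

  # second-derivative-of-gaussian pulse: spectral peak at sqrt(2)/(2 pi sigma)
  sg <- 2e-6
  mu <- 100e-6
  p <- dnorm(t, mu, sg) * ((t - mu)^2 - sg^2) / sg^4
  tr2 <- pressure_trace(t, p)
  f_expect <- sqrt(2) / (2 * pi * sg)
  expect_equal(central_frequency(tr2, half_width = 20e-6)$f_central, f_expect,
               tolerance = 0.03)
  # -6 dB band brackets the peak
  cf <- central_frequency(tr2, half_width = 20e-6)
  expect_lt(cf$f_lo, cf$f_central)
  expect_gt(cf$f_hi, cf$f_central)

  expect_error(central_frequency(pressure_trace(t, 0 * t)), "all-zero")
  expect_error(central_frequency(pressure_trace(t[1:10], t[1:10])), "short")
})

test_that("pulse profiles integrate to one", {
  for (shape in c("gaussian", "rectangular")) {
    S <- protoacoustics:::sample_pulse(pulse_profile(10e-6, shape), 5e-8)
    expect_equal(sum(S) * 5e-8, 1, tolerance = 1e-12)
  }
  expect_error(pulse_profile(-1), "duration")
})
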