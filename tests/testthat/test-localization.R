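arr <- reference_sensors()

test_that("sensor_array enforces the 4-sensor minimum", {
  expect_error(sensor_array(arr$positions[1:3, ]), "minimum of 4")
  expect_warning(sensor_array(arr$positions), "coplanar")
  flat <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(10, 10, 0))
  expect_warning(sensor_array(flat), "not unique")
})

test_that("cross-correlation recovers integer and fractional delays", {
  dt <- 5e-8
  t <- (0:799) * dt
  sg <- 1.5e-6
  wave <- function(t0) dnorm(t, t0, sg) * ((t - t0)^2 - sg^2) / sg^4
  tpl <- pressure_trace(t[1:300], wave(6e-6)[1:300])

  # exact integer delay
  tr <- pressure_trace(t, wave(6e-6 + 57 * dt))
  expect_lt(abs(as.numeric(estimate_toa(tr, tpl)) - 57 * dt), 0.01 * dt)

  # half-sample delay (band-limited): within 0.1 sample
  tr2 <- pressure_trace(t, wave(6e-6 + 57.5 * dt))
  expect_lt(abs(as.numeric(estimate_toa(tr2, tpl)) - 57.5 * dt), 0.1 * dt)

  # uncorrelated white noise is flagged
  set.seed(11)
  noise <- pressure_trace(t, rnorm(length(t)))
  expect_warning(lag <- estimate_toa(noise, tpl), "unreliable")
  expect_true(is.na(lag))

  expect_error(estimate_toa(pressure_trace(t, 0 * t), tpl), "flat")
  bad <- pressure_trace((0:799) * 1e-7, wave(6e-6))
  expect_error(estimate_toa(bad, tpl), "sampling step")
  expect_error(estimate_toa(tpl, tr), "longer")
})

test_that("correct_toas handles constant and per-sensor modes", {
  toas <- c(10, 11, 12, 13) * 1e-6
  expect_equal(correct_toas(toas, 0), toas)
  shifted <- correct_toas(toas, 1.08e-6)
  # constant mode leaves TDOAs unchanged
  expect_equal(diff(shifted), diff(toas))
  vec <- c(1, 2, 3, 4) * 1e-7
  pv <- correct_toas(toas, vec)
  expect_equal(pv - toas, -vec)
  expect_error(correct_toas(toas, c(1, 2) * 1e-7), "per sensor")
})

test_that("noiseless TDOAs are recovered to numerical precision", {
  src <- c(-70, 20, 171.9)
  toas <- exact_toas(src, arr$positions)
  rec <- solve_position(arr, tdoa_set(toas))
  expect_true(rec$converged)
  expect_lt(localization_error(rec, src), 1e-6)

  # several sources inside the array hull
  for (s in list(c(-60, 15, 172.5), c(-40, 10, 173), c(-85, 25, 172))) {
    r <- solve_position(arr, tdoa_set(exact_toas(s, arr$positions)))
    expect_lt(localization_error(r, s), 1e-6)
  }
})

test_that("a centred source in a symmetric array with zero TDOAs is recovered", {
  pos <- rbind(c(1, 1, 1), c(-1, -1, 1), c(-1, 1, -1), c(1, -1, -1)) * 30
  a <- sensor_array(pos)
  rec <- solve_position(a, tdoa_set(rep(0, 4)), init = c(5, 5, 5))
  expect_lt(localization_error(rec, c(0, 0, 0)), 1e-6)
})

test_that("reconstruction is equivariant under joint translation", {
  src <- c(-70, 20, 171.9)
  toas <- exact_toas(src, arr$positions)
  shift <- c(100, -50, 30)
  arr2 <- suppressWarnings(sensor_array(sweep(arr$positions, 2, -shift)))
  rec2 <- solve_position(arr2, tdoa_set(toas))
  expect_lt(localization_error(rec2, src + shift), 1e-6)
})

test_that("four well-conditioned sensors suffice", {
  pos <- rbind(c(0, 0, 50), c(40, 0, -20), c(-20, 35, -20), c(-20, -35, -20))
  a <- sensor_array(pos)
  src <- c(3, -4, 6)
  rec <- solve_position(a, tdoa_set(exact_toas(src, pos)), init = c(0, 0, 0),
                        box = rbind(rep(-30, 3), rep(30, 3)))
  expect_lt(localization_error(rec, src), 1e-5)
})

test_that("error grows monotonically with TOA jitter", {
  src <- c(-70, 20, 171.9)
  toas <- exact_toas(src, arr$positions)
  sigmas <- c(0, 10e-9, 50e-9, 100e-9)
  set.seed(99)
  mean_err <- vapply(sigmas, function(s) {
    errs <- replicate(50, {
      r <- solve_position(arr, tdoa_set(toas + rnorm(6, 0, s)))
      localization_error(r, src)
    })
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_err) > 0))
})

test_that("localization_error is the euclidean distance", {
  expect_equal(localization_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(localization_error(c(2, 2, 3), c(1, 2, 3)), 1)
  # the two printed positions of the reference reconstruction
  expect_equal(localization_error(c(-69.60, 20.81, 172.30),
                                  c(-70.00, 20.00, 171.90)),
               0.99, tolerance = 0.01)
})
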