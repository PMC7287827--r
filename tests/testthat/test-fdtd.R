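# shared geometry: a strip of water with source and sensor on the mid-row
make_map <- function(dx = 0.5, layer = NULL, c_layer = 2800, nr = 70) {
  nc <- round(50 / dx) + 2 * 18
  speed <- matrix(1500, nr, nc)
  if (!is.null(layer)) { # layer columns given in mm from the source
    j0 <- 18 + round(layer[1] / dx)
    j1 <- 18 + round(layer[2] / dx)
    speed[, j0:j1] <- c_layer
  }
  medium_map_2d(speed, density = 1000, dx = dx)
}

burst <- function(n, dt, t0 = 2e-6, sg = 4e-7) {
  stats::dnorm((seq_len(n) - 1) * dt, t0, sg)
}

run_pair <- function(map, dist_mm, dt = 1.2e-7, n_steps = 350, ...) {
  dx <- map$dx
  src <- c(35, 20)
  sen <- c(35, 20 + round(dist_mm / dx))
  cfg <- fdtd_config(dt = dt, n_steps = n_steps)
  fdtd_run(map, src, burst(n_steps, dt), sen, cfg, ...)
}

test_that("zero waveform produces all-zero traces", {
  map <- make_map()
  cfg <- fdtd_config(dt = 2e-7, n_steps = 50)
  out <- fdtd_run(map, c(35, 20), numeric(50), c(35, 60), cfg)
  expect_true(all(out == 0))
})

test_that("CFL violation is refused with the bound", {
  map <- make_map()
  expect_error(fdtd_run(map, c(35, 20), 1, c(35, 60),
                        fdtd_config(dt = 1e-6, n_steps = 10)),
               "CFL")
})

test_that("homogeneous first arrival matches the ray time d/c", {
  map <- make_map(dx = 0.5)
  tr <- run_pair(map, 30)
  # arrival measured relative to the source burst's own threshold crossing
  t_src <- first_arrival(burst(350, 1.2e-7), dt = 1.2e-7)
  t_arr <- first_arrival(tr[, 1], attr(tr, "dt")) - t_src
  expect_lt(abs(t_arr - 30e-3 / 1500), 2 * 0.5e-3 / 1500)
})

test_that("a fast layer advances the arrival by the ray-model correction", {
  map0 <- make_map(dx = 0.5)
  map1 <- make_map(dx = 0.5, layer = c(12, 16)) # 4 mm of 2800 m/s bone
  t0 <- first_arrival(run_pair(map0, 30)[, 1], 1.2e-7)
  t1 <- first_arrival(run_pair(map1, 30)[, 1], 1.2e-7)
  oracle <- toa_correction(fluid_solid_interface(c_long = 2800,
                                                 layer_thickness = 4))
  expect_lt(abs((t0 - t1) - oracle), 2 * 0.5e-3 / 1500)
})

test_that("halving the grid pitch barely moves the first arrival", {
  t_coarse <- first_arrival(run_pair(make_map(dx = 1), 30)[, 1], 1.2e-7)
  t_fine <- first_arrival(run_pair(make_map(dx = 0.5), 30)[, 1], 1.2e-7)
  expect_lt(abs(t_coarse - t_fine), 1e-3 / 1500)
})

test_that("source and sensor are reciprocal in a lossless map", {
  map <- make_map(dx = 0.5, layer = c(12, 16))
  cfg <- fdtd_config(dt = 1.2e-7, n_steps = 330)
  a <- c(35, 20)
  b <- c(35, 80)
  wav <- burst(330, 1.2e-7)
  t_ab <- fdtd_run(map, a, wav, b, cfg)
  t_ba <- fdtd_run(map, b, wav, a, cfg)
  expect_lt(rms(t_ab - t_ba) / max(abs(t_ab)), 0.01)
})

test_that("domain energy decays after the source stops", {
  map <- make_map(dx = 1)
  cfg <- fdtd_config(dt = 2e-7, n_steps = 400)
  wav <- c(burst(40, 2e-7), numeric(360))
  out <- fdtd_run(map, c(35, 20), wav, c(35, 40), cfg, track_energy = TRUE)
  e <- attr(out, "energy")
  # once the wavefront has entered the sponge the energy decays away
  expect_lt(e[400], e[200])
  expect_lt(e[400], 0.1 * max(e))
})

test_that("first_arrival interpolates thresholds and refuses flat traces", {
  tr <- c(0, 0, 0, 0, 1, 1, 1)
  expect_equal(first_arrival(tr, dt = 1, threshold_fraction = 0.5), 3.5)
  # delayed delta: within one sample of its delay
  d <- c(numeric(9), 1)
  expect_lt(abs(first_arrival(d, dt = 2e-7, threshold_fraction = 0.5) -
                  9 * 2e-7), 2e-7)
  # monotone ramp: documented linear interpolation
  ramp <- seq(0, 1, by = 0.1)
  expect_equal(first_arrival(ramp, dt = 1, threshold_fraction = 0.25), 2.5)
  expect_error(first_arrival(numeric(10), dt = 1), "never crosses")
  expect_error(first_arrival(tr, dt = 1, threshold_fraction = 2), "threshold")
})

test_that("sources and sensors must sit inside the non-sponge region", {
  map <- make_map()
  expect_error(fdtd_run(map, c(2, 2), 1, c(35, 60),
                        fdtd_config(dt = 2e-7, n_steps = 10)),
               "non-sponge")
})
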