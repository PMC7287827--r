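#' 2-D heterogeneous acoustic medium map
#'
#' Cell-centred maps of sound speed and density on a square grid; the
#' adiabatic bulk modulus `rho * c^2` per cell follows. Used by the small
#' time-domain solver [fdtd_run()] for arrival-time and transmission
#' validation (a 2-D solver spreads cylindrically, so amplitudes are not
#' compared against the 3-D ray model).
#'
#' @param speed matrix of sound speeds (m/s).
#' @param density matrix of densities (kg/m^3), same shape as `speed`, or a
#'   scalar.
#' @param dx grid pitch (mm).
#' @return object of class `medium_map_2d`.
#' @export
medium_map_2d <- function(speed, density = 1000, dx = 0.5) {
  if (is.matrix(density) && !all(dim(density) == dim(speed)))
    stop_domain("speed and density shapes differ")
  if (!is.matrix(density)) density <- matrix(density, nrow(speed), ncol(speed))
  if (any(speed <= 0) || any(density <= 0))
    stop_domain("speed and density must be positive everywhere")
  structure(list(speed = speed, density = density, dx = dx,
                 bulk = density * speed^2),
            class = "medium_map_2d")
}

#' FDTD run configuration
#'
#' @param dt time step (s); must satisfy the CFL bound
#'   `dt <= dx / (c_max * sqrt(2))`.
#' @param n_steps number of time steps.
#' @param sponge_width absorbing boundary width (cells).
#' @param sponge_strength peak damping per step at the outer edge.
#' @return object of class `fdtd_config`.
#' @export
fdtd_config <- function(dt, n_steps, sponge_width = 16, sponge_strength = 0.3) {
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 sponge_width = as.integer(sponge_width),
                 sponge_strength = sponge_strength),
            class = "fdtd_config")
}

#' Time-domain finite-difference acoustic solver (2-D)
#'
#' Integrates the heterogeneous acoustic wave equation
#' \deqn{\frac{1}{\rho c^2}\frac{\partial^2 p}{\partial t^2} =
#'   \nabla\cdot\left(\frac{1}{\rho}\nabla p\right)}
#' (monopole and dipole domain sources taken as zero; the source enters as a
#' pressure injection in the listed cells) with second-order central
#' differences, harmonic-mean face densities, and an exponential sponge
#' layer at the boundary.
#'
#' @param map a [medium_map_2d()].
#' @param source_cells integer matrix (n x 2) of (row, col) source cells.
#' @param source_waveform injected pressure per step (Pa); recycled/truncated
#'   to `n_steps`.
#' @param sensor_cells integer matrix (n x 2) of sensor cells.
#' @param cfg an [fdtd_config()].
#' @param track_energy if `TRUE`, also record `sum(p^2)` over the domain per
#'   step (attribute `"energy"`), a cheap diagnostic of sponge absorption.
#' @return matrix `n_steps x n_sensors` of pressure traces, with the time
#'   step as attribute `dt`.
#' @export
fdtd_run <- function(map, source_cells, source_waveform, sensor_cells, cfg,
                     track_energy = FALSE) {
  dx_m <- map$dx * 1e-3
  cmax <- max(map$speed)
  cfl <- dx_m / (cmax * sqrt(2))
  if (cfg$dt > cfl)
    stop_domain("CFL violated: dt = ", cfg$dt, " s exceeds dx/(c_max*sqrt(2)) = ",
                format(cfl), " s")
  source_cells <- rbind(source_cells)
  sensor_cells <- rbind(sensor_cells)
  nr <- nrow(map$speed); nc <- ncol(map$speed)
  sw <- cfg$sponge_width
  if (any(source_cells <= sw) || any(sensor_cells <= sw) ||
      any(source_cells[, 1] > nr - sw) || any(source_cells[, 2] > nc - sw) ||
      any(sensor_cells[, 1] > nr - sw) || any(sensor_cells[, 2] > nc - sw))
    stop_domain("sources and sensors must lie inside the non-sponge region")

  rho <- map$density
  # harmonic-mean 1/rho on faces
  bi <- 2 / (rho[-nr, ] + rho[-1, ])   # (nr-1) x nc : faces between rows
  bj <- 2 / (rho[, -nc] + rho[, -1])   # nr x (nc-1)
  scale <- map$bulk * (cfg$dt / dx_m)^2

  # sponge damping mask
  prof <- function(n, w, s) {
    d <- pmin(pmin(seq_len(n) - 1, n - seq_len(n)), w)
    exp(-s * ((w - d) / w)^2)
  }
  damp <- outer(prof(nr, sw, cfg$sponge_strength), prof(nc, sw, cfg$sponge_strength))

  wav <- rep(source_waveform, length.out = cfg$n_steps)
  src_idx <- (source_cells[, 2] - 1) * nr + source_cells[, 1]
  sen_idx <- (sensor_cells[, 2] - 1) * nr + sensor_cells[, 1]

  p0 <- matrix(0, nr, nc); p1 <- p0
  out <- matrix(0, cfg$n_steps, nrow(sensor_cells))
  energy <- if (track_energy) numeric(cfg$n_steps) else NULL
  for (n in seq_len(cfg$n_steps)) {
    lap <- matrix(0, nr, nc)
    fi <- bi * (p1[-1, ] - p1[-nr, ])          # flux across row faces
    lap[-nr, ] <- lap[-nr, ] + fi
    lap[-1, ] <- lap[-1, ] - fi
    fj <- bj * (p1[, -1] - p1[, -nc])
    lap[, -nc] <- lap[, -nc] + fj
    lap[, -1] <- lap[, -1] - fj
    p2 <- 2 * p1 - p0 + scale * lap
    p2[src_idx] <- p2[src_idx] + wav[n]
    p2 <- p2 * damp
    p1 <- p1 * damp # damp both levels to avoid sponge-edge ringing
    out[n, ] <- p2[sen_idx]
    if (track_energy) energy[n] <- sum(p2^2)
    p0 <- p1; p1 <- p2
  }
  attr(out, "dt") <- cfg$dt
  if (track_energy) attr(out, "energy") <- energy
  out
}

#' First-arrival time of a trace
#'
#' Time of the first crossing of `threshold_fraction * max(|trace|)`, with
#' linear interpolation between the bracketing samples.
#'
#' @param trace numeric vector (a single sensor trace).
#' @param dt time step (s); taken from `attr(trace, "dt")` if missing.
#' @param threshold_fraction fraction of the peak magnitude, in (0, 1).
#' @return first-arrival time (s).
#' @export
first_arrival <- function(trace, dt = attr(trace, "dt"), threshold_fraction = 0.1) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop_domain("threshold_fraction must be in (0, 1)")
  a <- abs(as.numeric(trace))
  thr <- threshold_fraction * max(a)
  if (max(a) == 0 || all(a < thr)) stop_domain("trace never crosses the threshold")
  k <- which(a >= thr)[1]
  if (k == 1) return(0)
  frac <- (thr - a[k - 1]) / (a[k] - a[k - 1])
  (k - 2 + frac) * dt
}
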