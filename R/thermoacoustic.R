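#' Acoustic medium properties
#'
#' Defaults describe body-temperature water (the cerebrospinal fluid / brain
#' stand-in): sound speed 1500 m/s, specific heat 4180 J/(kg K), volumetric
#' thermal expansion 3.7e-4 1/K (37 C water), density 1003 kg/m^3, and a
#' frequency-independent absorption of 0.95 Np/m referenced to 300 kHz.
#'
#' @param cs sound speed (m/s).
#' @param Cp specific heat (J/(kg K)).
#' @param alpha_thermal volumetric thermal expansion coefficient (1/K).
#' @param rho density (kg/m^3).
#' @param alpha_atten absorption coefficient (Np/m at the reference frequency).
#' @return object of class `acoustic_medium`.
#' @export
acoustic_medium <- function(cs = 1500, Cp = 4180, alpha_thermal = 3.7e-4,
                            rho = 1003, alpha_atten = 0.95) {
  vals <- c(cs = cs, Cp = Cp, alpha_thermal = alpha_thermal, rho = rho,
            alpha_atten = alpha_atten)
  if (any(vals <= 0)) stop_domain("all medium properties must be > 0")
  structure(as.list(vals), class = "acoustic_medium")
}

#' Beam pulse time profile
#'
#' The deposition time profile S(t), normalized so its time integral is 1.
#' Both shapes are supported on `[0, duration]`:
#' * `gaussian` (default): a Gaussian of sigma = duration/6 centred at
#'   duration/2, shifted down by its edge value so the profile reaches zero
#'   continuously at both ends, and renormalized;
#' * `rectangular`: constant `1/duration`.
#'
#' @param duration total pulse duration (s).
#' @param shape `"gaussian"` or `"rectangular"`.
#' @return object of class `pulse_profile`.
#' @export
pulse_profile <- function(duration = 10e-6, shape = c("gaussian", "rectangular")) {
  shape <- match.arg(shape)
  if (duration <= 0) stop_domain("pulse duration must be > 0")
  structure(list(duration = duration, shape = shape), class = "pulse_profile")
}

# sample S(t) on a dt grid over [0, duration]; sum(S)*dt == 1
sample_pulse <- function(pulse, dt) {
  n <- max(2L, round(pulse$duration / dt))
  t <- (seq_len(n) - 0.5) * dt
  S <- switch(pulse$shape,
    rectangular = rep(1 / pulse$duration, n),
    gaussian = pmax(0, stats::dnorm(t, pulse$duration / 2, pulse$duration / 6) -
                      stats::dnorm(0, pulse$duration / 2, pulse$duration / 6)))
  S / (sum(S) * dt)
}

#' Sampled pressure time series
#'
#' @param t time axis (s), uniform.
#' @param p pressure (Pa), same length as `t`.
#' @param observation_point position of the observation (mm, length 3).
#' @return object of class `pressure_trace`.
#' @export
pressure_trace <- function(t, p, observation_point = c(NA, NA, NA)) {
  if (length(t) != length(p)) stop_domain("t and p must have equal length")
  dt <- t[2] - t[1]
  if (dt <= 0) stop_domain("time step must be > 0")
  structure(list(t = t, p = p, dt = dt, observation_point = observation_point),
            class = "pressure_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat("<pressure_trace> ", length(x$p), " samples, dt = ", format(x$dt),
      " s, peak |p| = ", format(max(abs(x$p)), digits = 4), " Pa\n", sep = "")
  invisible(x)
}

#' Thermoacoustic pressure at a point
#'
#' Discretizes the retarded-time thermoacoustic integral
#' \deqn{p(r,t) = \frac{\alpha}{4\pi C_p} \int \frac{dV'}{|r-r'|}
#'   \frac{\partial^2}{\partial t^2} \epsilon(r', t - |r-r'|/c_s)}
#' under the separable source assumption
#' \eqn{\epsilon(r,t) = \epsilon(r) S_{cum}(t)}: each voxel contributes
#' weight \eqn{\epsilon\, dV'/|r-r'|} at its retarded time, the binned
#' kernel is convolved with the sampled pulse profile and differentiated
#' once by central differences (equivalent to the second time derivative of
#' the cumulative deposition).
#'
#' Voxels closer to the observation point than `near_field_factor` voxel
#' pitches are subdivided 4x4x4 so the point-voxel approximation stays
#' accurate in the near field.
#'
#' @param dose a [dose_grid()] (coordinates of `obs` are in its frame).
#' @param obs observation point (mm, length 3).
#' @param medium an [acoustic_medium()].
#' @param pulse a [pulse_profile()].
#' @param dt sampling step (s); must satisfy `dt <= min(spacing)/cs`.
#' @param t_max optional trace length (s); default covers the farthest voxel
#'   plus two pulse durations.
#' @param arrival_advance time (s) subtracted from every retarded arrival,
#'   used by scene code to emulate the faster path through the skull layer.
#' @param near_field_factor subdivision radius in units of voxel pitch.
#' @return a [pressure_trace()].
#' @export
thermoacoustic_pressure <- function(dose, obs, medium = acoustic_medium(),
                                    pulse = pulse_profile(), dt = 5e-8,
                                    t_max = NULL, arrival_advance = 0,
                                    near_field_factor = 8) {
  h <- min(dose$spacing)
  dt_bound <- h * 1e-3 / medium$cs
  if (dt > dt_bound)
    stop_domain("dt = ", dt, " s too coarse for retarded-time binning; ",
                "need dt <= min(spacing)/cs = ", format(dt_bound), " s")

  idx <- which(dose$values > 0, arr.ind = TRUE)
  ax <- lapply(1:3, function(k) grid_axis(dose, k))
  n_t <- if (is.null(t_max)) NULL else ceiling(t_max / dt)

  if (nrow(idx) == 0) {
    n <- n_t %||% 64L
    return(pressure_trace((seq_len(n) - 1) * dt, numeric(n), obs))
  }

  pts <- cbind(ax[[1]][idx[, 1]], ax[[2]][idx[, 2]], ax[[3]][idx[, 3]])
  eJ <- dose$values[idx] * prod(dose$spacing) * 1e-9 # J per voxel
  d <- sqrt(colSums((t(pts) - obs)^2)) # mm

  near <- d < near_field_factor * max(dose$spacing)
  if (any(near)) {
    sub <- sub_divide(pts[near, , drop = FALSE], eJ[near], dose$spacing, 4L)
    pts <- rbind(pts[!near, , drop = FALSE], sub$pts)
    eJ <- c(eJ[!near], sub$eJ)
    d <- sqrt(colSums((t(pts) - obs)^2))
  }
  d <- pmax(d, 1e-6) # observation inside a source subvoxel
  w <- eJ / (d * 1e-3) # J/m
  tt <- d * 1e-3 / medium$cs - arrival_advance

  n <- n_t %||% (ceiling((max(tt) + 2 * pulse$duration) / dt) + 2L)
  B <- numeric(n + 1)
  fi <- tt / dt + 1
  fi <- pmin(pmax(fi, 1), n - 1)
  i0 <- floor(fi)
  fr <- fi - i0
  for (grp in split(seq_along(w), i0)) { # vectorized accumulate
    i <- i0[grp[1]]
    B[i] <- B[i] + sum(w[grp] * (1 - fr[grp]))
    B[i + 1] <- B[i + 1] + sum(w[grp] * fr[grp])
  }
  S <- sample_pulse(pulse, dt)
  q <- stats::convolve(B, rev(S), type = "open")[seq_len(n)]
  p <- c(0, diff(q, lag = 2) / (2 * dt), 0) * medium$alpha_thermal / (4 * pi * medium$Cp)
  pressure_trace((seq_len(n) - 1) * dt, p, obs)
}

# split voxels into k^3 equal-energy subcells
sub_divide <- function(pts, eJ, spacing, k) {
  off <- lapply(1:3, function(a) ((seq_len(k) - 0.5) / k - 0.5) * spacing[a])
  g <- as.matrix(expand.grid(off[[1]], off[[2]], off[[3]]))
  n <- nrow(pts)
  m <- nrow(g)
  list(pts = pts[rep(seq_len(n), each = m), , drop = FALSE] +
         g[rep(seq_len(m), n), , drop = FALSE],
       eJ = rep(eJ / m, each = m))
}

#' Spherical spreading with absorption
#'
#' `P = P_ref * (d_ref / d) * exp(-alpha_atten * (d - d_ref))`, the
#' ray-acoustic amplitude of a spherical wave propagated from a reference
#' distance with a frequency-independent absorption coefficient (distances
#' converted to metres inside the exponent).
#'
#' @param P_ref reference amplitude (Pa) at `d_ref`.
#' @param d_ref reference distance (mm, > 0).
#' @param d target distances (mm, all `>= d_ref`), vectorized.
#' @param alpha_atten absorption coefficient (Np/m).
#' @return amplitudes (Pa) at `d`.
#' @export
attenuated_amplitude <- function(P_ref, d_ref, d, alpha_atten = 0.95) {
  if (d_ref <= 0) stop_domain("d_ref must be > 0")
  if (any(d < d_ref)) stop_domain("d < d_ref: no back-propagation")
  P_ref * (d_ref / d) * exp(-alpha_atten * (d - d_ref) * 1e-3)
}

#' Maximum pressure versus distance
#'
#' Tabulates [attenuated_amplitude()] over a set of sensor distances.
#'
#' @inheritParams attenuated_amplitude
#' @param distances sorted ascending distances (mm).
#' @return data.frame with `distance_mm` and `pressure_Pa` (strictly
#'   decreasing).
#' @export
max_pressure_vs_distance <- function(P_ref, d_ref, distances, alpha_atten = 0.95) {
  if (is.unsorted(distances, strictly = FALSE))
    stop_domain("distances must be sorted ascending")
  data.frame(distance_mm = distances,
             pressure_Pa = attenuated_amplitude(P_ref, d_ref, distances, alpha_atten))
}

#' Central frequency of a pressure trace
#'
#' Frequency of the maximum of the amplitude spectrum after mean removal and
#' a Hann taper. By default the analysis window is centred on the envelope
#' peak with half-width `half_width`, which isolates the direct (spherical)
#' Bragg-peak arrival from the later cylindrical track wave; set
#' `half_width = Inf` to analyse the whole trace. The windowed segment is
#' zero-padded (`pad_factor`) for peak interpolation.
#'
#' @param trace a [pressure_trace()] with at least 64 samples.
#' @param half_width analysis half-window around the peak (s).
#' @param pad_factor zero-padding factor for the FFT.
#' @param f_max upper frequency bound of the search (Hz).
#' @return list with `f_central` (Hz) and the -6 dB band edges `f_lo`,
#'   `f_hi` (Hz).
#' @export
central_frequency <- function(trace, half_width = 10e-6, pad_factor = 8,
                              f_max = Inf) {
  if (length(trace$p) < 64) stop_domain("trace too short (need >= 64 samples)")
  if (max(abs(trace$p)) == 0) stop_domain("all-zero trace: central frequency undefined")
  ipk <- which.max(abs(trace$p))
  nh <- if (is.finite(half_width)) round(half_width / trace$dt) else length(trace$p)
  i0 <- max(1, ipk - nh)
  i1 <- min(length(trace$p), ipk + nh)
  x <- trace$p[i0:i1]
  x <- x - mean(x)
  m <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(m - 1)) / (m - 1))
  xz <- c(x * w, numeric((pad_factor - 1) * m))
  A <- Mod(stats::fft(xz))
  f <- (seq_along(xz) - 1) / (length(xz) * trace$dt)
  sel <- f > 0 & f <= min(f_max, 0.5 / trace$dt)
  fc <- f[sel][which.max(A[sel])]
  amax <- max(A[sel])
  above <- sel & A >= amax / 2 # -6 dB on amplitude
  list(f_central = fc, f_lo = min(f[above]), f_hi = max(f[above]))
}
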