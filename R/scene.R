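#' Six-sensor head array (printed reference geometry)
#'
#' The six sensor positions of the reference head scene, in mm. The array is
#' nearly coplanar in z (all sensors within 2.6 mm of the same axial plane),
#' which makes the reconstruction ill-conditioned along z; see
#' [sensor_array()]. A JSON copy ships in
#' `system.file("extdata", "table1_sensors.json", package = "protoacoustics")`.
#'
#' @param exclude optional indices to drop (the fix must keep >= 4 sensors).
#' @return a [sensor_array()].
#' @export
reference_sensors <- function(exclude = NULL) {
  pos <- rbind(
    c(-111.7, 1.1, 172.2),
    c(-11.1, 13.8, 172.1),
    c(-10.9, 29.8, 171.5),
    c(-10.1, 1.0, 174.0),
    c(-10.1, 15.6, 174.1),
    c(-100.0, 33.5, 173.4))
  labels <- paste0("S", 1:6)
  if (!is.null(exclude)) {
    pos <- pos[-exclude, , drop = FALSE]
    labels <- labels[-exclude]
  }
  suppressWarnings(sensor_array(pos, labels))
}

#' Layered head scene
#'
#' The simulation scene: a spherical skull shell filled with
#' water-equivalent brain fluid, a proton beam whose Bragg peak is the
#' acoustic source, and a sensor array on/outside the shell. Defaults
#' reproduce the reference geometry: the six printed sensors, a 100 MeV /
#' 5e6 proton / 10 us pulse beam travelling along +x whose peak centroid
#' lands at `source_target`, and a shell centred at the midpoint of the
#' sensor span with outer radius 42 mm (the largest sphere keeping every
#' sensor on or outside the shell) and the default 3.5 mm skull.
#'
#' @param sensors a [sensor_array()].
#' @param beam a [beam_config()].
#' @param medium an [acoustic_medium()] (shell interior).
#' @param iface a [fluid_solid_interface()] (shell wall).
#' @param skull_center shell centre (mm).
#' @param skull_outer_radius outer shell radius (mm).
#' @param source_target where the Bragg-peak centroid is placed (mm).
#' @param source_diameter diameter (mm) of the spherical region around the
#'   peak centroid used as the acoustic source for sensor traces.
#' @param template_distance distance (mm) beyond the peak, on the beam axis,
#'   of the reference observation point (the emitted-signal template).
#' @return object of class `layered_scene`.
#' @export
layered_scene <- function(sensors = reference_sensors(),
                          beam = beam_config(direction = c(1, 0, 0)),
                          medium = acoustic_medium(),
                          iface = fluid_solid_interface(),
                          skull_center = c(-61, 17, 172.5),
                          skull_outer_radius = 42,
                          source_target = c(-70, 20, 171.9),
                          source_diameter = 2,
                          template_distance = 20) {
  inner <- skull_outer_radius - iface$layer_thickness
  if (sqrt(sum((source_target - skull_center)^2)) >= inner)
    stop_domain("source must lie inside the inner shell surface")
  dsen <- sqrt(colSums((t(sensors$positions) - skull_center)^2))
  if (any(dsen < skull_outer_radius - 1e-6))
    stop_domain("all sensors must lie on or outside the outer shell surface")
  structure(list(sensors = sensors, beam = beam, medium = medium,
                 iface = iface, skull_center = skull_center,
                 skull_outer_radius = skull_outer_radius,
                 skull_inner_radius = inner,
                 source_target = source_target,
                 source_diameter = source_diameter,
                 template_distance = template_distance),
            class = "layered_scene")
}

#' @rdname layered_scene
#' @export
build_default_scene <- function() layered_scene()

#' @export
print.layered_scene <- function(x, ...) {
  d <- sqrt(colSums((t(x$sensors$positions) - x$source_target)^2))
  cat("<layered_scene>\n",
      "  beam: ", x$beam$energy, " MeV, ", format(x$beam$n_protons),
      " protons, sigma ", x$beam$sigma_lateral, " mm\n",
      "  skull shell: centre (", paste(x$skull_center, collapse = ", "),
      ") mm, R ", x$skull_inner_radius, "-", x$skull_outer_radius, " mm\n",
      "  ", nrow(x$sensors$positions), " sensors, ",
      format(min(d), digits = 3), "-", format(max(d), digits = 3),
      " mm from the source\n", sep = "")
  invisible(x)
}

# incidence angle (rad) at the inner shell surface of the ray source->point
shell_incidence <- function(scene, point) {
  u <- point - scene$source_target
  L <- sqrt(sum(u^2))
  u <- u / L
  oc <- scene$source_target - scene$skull_center
  b <- sum(u * oc)
  disc <- b^2 - (sum(oc^2) - scene$skull_inner_radius^2)
  tq <- -b + sqrt(disc) # ray starts inside: take the outgoing root
  hit <- scene$source_target + tq * u
  nrm <- (hit - scene$skull_center) / scene$skull_inner_radius
  acos(min(1, abs(sum(u * nrm))))
}

#' Per-sensor skull-layer arrival advances
#'
#' For each sensor, the incidence angle of the source-to-sensor ray on the
#' inner shell surface and the corresponding [toa_correction()] magnitude
#' (the amount by which the layer makes the arrival earlier).
#'
#' @param scene a [layered_scene()].
#' @return data.frame with `sensor`, `theta_i_deg`, `advance_s`.
#' @export
layer_advances <- function(scene) {
  n <- nrow(scene$sensors$positions)
  th <- vapply(seq_len(n), function(i)
    shell_incidence(scene, scene$sensors$positions[i, ]), numeric(1))
  adv <- vapply(th, function(t) toa_correction(scene$iface, t), numeric(1))
  data.frame(sensor = scene$sensors$labels, theta_i_deg = th * 180 / pi,
             advance_s = adv)
}

#' Run the full monitoring chain
#'
#' Executes dose deposition, thermoacoustic emission, propagation through
#' the skull shell, cross-correlation arrival-time estimation, layer time
#' correction, and TDOA reconstruction on a scene:
#'
#' 1. deposit the pulse on a beam-local grid ([deposit_3d()]);
#' 2. locate the Bragg peak ([peak_region()]) and map its centroid onto the
#'    scene's source target (this defines the true source position);
#' 3. generate sensor traces with [thermoacoustic_pressure()] from the dose
#'    inside the source sphere, each arrival advanced by its per-sensor
#'    skull-layer time ([layer_advances()]) and scaled by the interface
#'    power transmission and fluid absorption;
#' 4. estimate per-sensor lags against the source-side template trace
#'    (observation `template_distance` mm beyond the peak on the beam axis)
#'    by [estimate_toa()];
#' 5. if `correction` is on, remove the (negative) layer shifts with
#'    [correct_toas()] — constant or per-sensor mode;
#' 6. solve the TDOA system with [solve_position()] and report the
#'    localization error against the true source.
#'
#' Optional Gaussian TOA jitter (`toa_jitter_sd`, seconds) is added to the
#' estimated lags for degradation studies; the chain is deterministic when
#' it is zero.
#'
#' @param scene a [layered_scene()].
#' @param spacing dose-grid voxel pitch (mm); 0.5 mm resolves the 2 mm
#'   source sphere.
#' @param dt trace sampling step (s).
#' @param correction `"per_sensor"` (default), `"constant"` (the
#'   normal-incidence value applied to every sensor; cancels in TDOAs), or
#'   `"none"`.
#' @param toa_jitter_sd standard deviation of added TOA noise (s).
#' @param seed RNG seed (used only when `toa_jitter_sd > 0`).
#' @return a `run_report` list: `dose_grid`, `peak`, `true_source`,
#'   `advances`, `template`, `traces`, `lags`, `toas_corrected`,
#'   `reconstruction`, `error_mm`, `config`.
#' @export
run_full_chain <- function(scene, spacing = 0.5, dt = 5e-8,
                           correction = c("per_sensor", "constant", "none"),
                           toa_jitter_sd = 0, seed = NULL) {
  correction <- match.arg(correction)
  if (!is.null(seed)) set.seed(seed)

  ## 1. dose in beam-local coordinates (beam along local +z)
  grid <- deposit_3d(scene$beam, spacing = spacing)
  pk <- peak_region(grid, 0.5)

  ## 2. local -> global map: local z axis onto the beam direction,
  ##    peak centroid onto the scene source target
  R <- rotation_to(scene$beam$direction)
  to_global <- function(loc) {
    sweep(loc %*% t(R), 2, scene$source_target +
            as.numeric(R %*% (-pk$centroid)), FUN = "+")
  }
  true_source <- scene$source_target

  ## 3. source sphere voxels
  idx <- which(grid$values > 0, arr.ind = TRUE)
  axl <- lapply(1:3, function(k) grid_axis(grid, k))
  pts <- cbind(axl[[1]][idx[, 1]], axl[[2]][idx[, 2]], axl[[3]][idx[, 3]])
  inside <- sqrt(colSums((t(pts) - pk$centroid)^2)) <= scene$source_diameter / 2
  src_pts <- to_global(pts[inside, , drop = FALSE])
  src_eJ <- grid$values[idx][inside] * prod(grid$spacing) * 1e-9

  adv <- layer_advances(scene)
  pulse <- pulse_profile(scene$beam$pulse_duration, scene$beam$pulse_shape)

  ## template: source-side trace on the beam axis beyond the peak (all fluid)
  tpl_obs <- true_source + scene$beam$direction * scene$template_distance
  template <- point_cloud_pressure(src_pts, src_eJ, tpl_obs, scene$medium,
                                   pulse, dt)

  ## sensor traces: layer advance + transmission/attenuation amplitude scale
  n <- nrow(scene$sensors$positions)
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    sen <- scene$sensors$positions[i, ]
    tr <- point_cloud_pressure(src_pts, src_eJ, sen, scene$medium, pulse, dt,
                               arrival_advance = adv$advance_s[i])
    pc <- power_coefficients(adv$theta_i_deg[i] * pi / 180, scene$iface)
    dist <- sqrt(sum((sen - true_source)^2))
    tr$p <- tr$p * pc$T_p * exp(-scene$medium$alpha_atten * dist * 1e-3)
    traces[[i]] <- tr
  }

  ## 4. lags by cross-correlation against the template
  lags <- vapply(traces, function(tr) as.numeric(estimate_toa(tr, template)),
                 numeric(1))
  if (toa_jitter_sd > 0) lags <- lags + stats::rnorm(n, 0, toa_jitter_sd)

  ## 5. layer correction: the layer shift is -advance (arrivals earlier)
  toas <- switch(correction,
    per_sensor = correct_toas(lags, -adv$advance_s),
    constant = correct_toas(lags, -rep(toa_correction(scene$iface, 0), n)),
    none = lags)

  ## 6. TDOA solve
  td <- tdoa_set(toas, ref = 1L, c_sound = scene$medium$cs)
  box <- rbind(scene$skull_center - scene$skull_inner_radius,
               scene$skull_center + scene$skull_inner_radius)
  rec <- solve_position(scene$sensors, td, init = scene$skull_center, box = box)

  structure(list(dose_grid = grid, peak = pk, true_source = true_source,
                 advances = adv, template = template, traces = traces,
                 lags = lags, toas_corrected = toas, reconstruction = rec,
                 error_mm = localization_error(rec, true_source),
                 config = list(spacing = spacing, dt = dt,
                               correction = correction,
                               toa_jitter_sd = toa_jitter_sd, seed = seed)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n",
      "  true source: (", paste(sprintf("%.2f", x$true_source), collapse = ", "),
      ") mm\n  reconstructed: (",
      paste(sprintf("%.2f", x$reconstruction$position), collapse = ", "),
      ") mm\n  localization error: ", sprintf("%.3f", x$error_mm), " mm ",
      "(correction: ", x$config$correction, ")\n", sep = "")
  invisible(x)
}

# rotation matrix mapping the local +z axis onto unit vector v
rotation_to <- function(v) {
  z <- c(0, 0, 1)
  if (sum((v - z)^2) < 1e-12) return(diag(3))
  if (sum((v + z)^2) < 1e-12) return(diag(c(1, -1, -1)))
  axis <- c(z[2] * v[3] - z[3] * v[2], z[3] * v[1] - z[1] * v[3],
            z[1] * v[2] - z[2] * v[1])
  s <- sqrt(sum(axis^2))
  cth <- sum(z * v)
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

# thermoacoustic trace from an explicit point-source cloud (global mm
# coordinates, energies in J); shares the kernel of thermoacoustic_pressure
point_cloud_pressure <- function(pts, eJ, obs, medium, pulse, dt,
                                 arrival_advance = 0) {
  d <- pmax(sqrt(colSums((t(pts) - obs)^2)), 1e-6)
  w <- eJ / (d * 1e-3)
  tt <- d * 1e-3 / medium$cs - arrival_advance
  n <- ceiling((max(tt) + 2 * pulse$duration) / dt) + 2L
  B <- numeric(n + 1)
  fi <- pmin(pmax(tt / dt + 1, 1), n - 1)
  i0 <- floor(fi)
  fr <- fi - i0
  for (grp in split(seq_along(w), i0)) {
    i <- i0[grp[1]]
    B[i] <- B[i] + sum(w[grp] * (1 - fr[grp]))
    B[i + 1] <- B[i + 1] + sum(w[grp] * fr[grp])
  }
  S <- sample_pulse(pulse, dt)
  q <- stats::convolve(B, rev(S), type = "open")[seq_len(n)]
  p <- c(0, diff(q, lag = 2) / (2 * dt), 0) *
    medium$alpha_thermal / (4 * pi * medium$Cp)
  pressure_trace((seq_len(n) - 1) * dt, p, obs)
}
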