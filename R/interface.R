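#' Cerebrospinal-fluid / skull interface
#'
#' Plane-wave description of the fluid-solid boundary between the
#' cerebrospinal fluid and the skull bone. Default skull parameters
#' (longitudinal 2800 m/s, shear 1400 m/s, density 1900 kg/m^3, thickness
#' 3.5 mm) are literature-typical cranial-bone values chosen so that the
#' normal-incidence arrival-time correction equals 1.08 us; all are
#' configurable.
#'
#' @param c_fluid fluid sound speed (m/s).
#' @param c_long skull longitudinal speed (m/s), `> c_fluid` here.
#' @param c_shear skull shear speed (m/s), `< c_long`.
#' @param rho_fluid,rho_solid densities (kg/m^3).
#' @param layer_thickness skull thickness (mm).
#' @return object of class `fluid_solid_interface`.
#' @export
fluid_solid_interface <- function(c_fluid = 1500, c_long = 2800, c_shear = 1400,
                                  rho_fluid = 1003, rho_solid = 1900,
                                  layer_thickness = 3.5) {
  if (!(c_long > c_shear && c_shear > 0)) stop_domain("need c_long > c_shear > 0")
  if (layer_thickness < 0) stop_domain("layer thickness must be >= 0")
  structure(list(c_fluid = c_fluid, c_long = c_long, c_shear = c_shear,
                 rho_fluid = rho_fluid, rho_solid = rho_solid,
                 layer_thickness = layer_thickness),
            class = "fluid_solid_interface")
}

#' Snell refraction angles at the fluid-solid interface
#'
#' `sin(theta_p) = (c_long/c_fluid) sin(theta_i)` for the transmitted
#' longitudinal wave and `sin(theta_s) = (c_shear/c_fluid) sin(theta_i)` for
#' the mode-converted shear wave. Past the corresponding critical angle the
#' wave is evanescent and its angle is `NA`.
#'
#' @param theta_i incidence angle (rad), in `[0, pi/2)`.
#' @param iface a [fluid_solid_interface()].
#' @return list with `theta_p`, `theta_s` (rad or `NA`), and logical flags
#'   `evanescent_p`, `evanescent_s`.
#' @export
snell_angles <- function(theta_i, iface = fluid_solid_interface()) {
  if (theta_i < 0 || theta_i >= pi / 2) stop_domain("theta_i must be in [0, pi/2)")
  sp <- (iface$c_long / iface$c_fluid) * sin(theta_i)
  ss <- (iface$c_shear / iface$c_fluid) * sin(theta_i)
  list(theta_p = if (sp < 1) asin(sp) else NA_real_,
       theta_s = if (ss < 1) asin(ss) else NA_real_,
       evanescent_p = sp >= 1, evanescent_s = ss >= 1)
}

#' Critical angle of a transmitted wave type
#'
#' @param iface a [fluid_solid_interface()].
#' @param wave `"longitudinal"` or `"shear"`.
#' @return critical incidence angle (rad), or `pi/2` if the transmitted
#'   speed does not exceed the fluid speed.
#' @export
critical_angle <- function(iface = fluid_solid_interface(),
                           wave = c("longitudinal", "shear")) {
  wave <- match.arg(wave)
  ct <- if (wave == "longitudinal") iface$c_long else iface$c_shear
  if (ct <= iface$c_fluid) pi / 2 else asin(iface$c_fluid / ct)
}

#' Power transmission and reflection coefficients
#'
#' Energy-flux coefficients of the plane fluid-solid boundary with acoustic
#' impedances \eqn{Z = \rho c / \cos\theta}: with
#' \eqn{Z_{tot} = Z_p \cos^2 2\theta_s + Z_s \sin^2 2\theta_s},
#' \deqn{R = \left(\frac{Z_{tot} - Z_w}{Z_{tot} + Z_w}\right)^2,\quad
#'  T_p = \frac{4 Z_p Z_w \cos^2 2\theta_s}{(Z_{tot}+Z_w)^2},\quad
#'  T_s = \frac{4 Z_s Z_w \sin^2 2\theta_s}{(Z_{tot}+Z_w)^2}.}
#' Below both critical angles `T_p + T_s + R = 1` identically; past a
#' critical angle the corresponding transmitted power is 0, and past both
#' the boundary reflects totally.
#'
#' @inheritParams snell_angles
#' @return list with `T_p`, `T_s`, `R`, all in `[0, 1]`.
#' @export
power_coefficients <- function(theta_i, iface = fluid_solid_interface()) {
  sn <- snell_angles(theta_i, iface)
  if (sn$evanescent_p && sn$evanescent_s)
    return(list(T_p = 0, T_s = 0, R = 1))
  Zw <- iface$rho_fluid * iface$c_fluid / cos(theta_i)
  if (sn$evanescent_p) {
    # only shear transmits; longitudinal evanescent carries no mean flux
    Zs <- iface$rho_solid * iface$c_shear / cos(sn$theta_s)
    s2 <- sin(2 * sn$theta_s)^2
    Ztot <- Zs * s2
    Ts <- 4 * Zs * Zw * s2 / (Ztot + Zw)^2
    return(list(T_p = 0, T_s = Ts, R = 1 - Ts))
  }
  Zp <- iface$rho_solid * iface$c_long / cos(sn$theta_p)
  Zs <- iface$rho_solid * iface$c_shear / cos(sn$theta_s)
  c2 <- cos(2 * sn$theta_s)^2
  s2 <- sin(2 * sn$theta_s)^2
  Ztot <- Zp * c2 + Zs * s2
  denom <- (Ztot + Zw)^2
  list(T_p = 4 * Zp * Zw * c2 / denom,
       T_s = 4 * Zs * Zw * s2 / denom,
       R = (Ztot - Zw)^2 / denom)
}

#' Arrival-time correction for the skull layer
#'
#' Magnitude of the arrival-time advance caused by the faster longitudinal
#' path through the layer: the refracted ray crosses the layer along a
#' segment of length `L / cos(theta_p)`; the correction is the time that
#' segment would take at the fluid speed minus the time it takes at the
#' skull longitudinal speed,
#' \deqn{\Delta t = \frac{L}{\cos\theta_p}\left(\frac{1}{c_{fluid}} -
#'   \frac{1}{c_{long}}\right),}
#' which at normal incidence and the default interface equals 1.08 us.
#' The layer makes arrivals this much *earlier* than an all-fluid path;
#' scene code therefore uses `-toa_correction(...)` as the signed
#' layer-induced shift handed to [correct_toas()].
#'
#' @inheritParams snell_angles
#' @return time correction (s, `>= 0`).
#' @export
toa_correction <- function(iface = fluid_solid_interface(), theta_i = 0) {
  sn <- snell_angles(theta_i, iface)
  if (sn$evanescent_p)
    stop_domain("longitudinal wave evanescent at theta_i = ", round(theta_i, 4),
                " rad (critical angle ", round(critical_angle(iface), 4), " rad)")
  L <- iface$layer_thickness * 1e-3
  (L / cos(sn$theta_p)) * (1 / iface$c_fluid - 1 / iface$c_long)
}

#' Transmission table over incidence angles
#'
#' @param iface a [fluid_solid_interface()].
#' @param thetas_deg incidence angles in degrees.
#' @return data.frame with columns `theta_i_deg`, `theta_p_deg`,
#'   `theta_s_deg`, `T_p`, `T_s`, `R`.
#' @export
transmission_table <- function(iface = fluid_solid_interface(),
                               thetas_deg = seq(0, 80, by = 1)) {
  rows <- lapply(thetas_deg, function(td) {
    th <- td * pi / 180
    sn <- snell_angles(th, iface)
    pc <- power_coefficients(th, iface)
    data.frame(theta_i_deg = td,
               theta_p_deg = if (is.na(sn$theta_p)) NA else sn$theta_p * 180 / pi,
               theta_s_deg = if (is.na(sn$theta_s)) NA else sn$theta_s * 180 / pi,
               T_p = pc$T_p, T_s = pc$T_s, R = pc$R)
  })
  do.call(rbind, rows)
}
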