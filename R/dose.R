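#' Proton beam configuration
#'
#' Describes one beam pulse: a monoenergetic pencil beam with a lateral
#' Gaussian profile and a finite time profile. The validated energy band of
#' the analytic depth-dose model is 80-150 MeV; energies outside it are
#' accepted with a warning.
#'
#' @param energy beam energy in MeV.
#' @param n_protons protons per pulse.
#' @param sigma_lateral lateral Gaussian beam width (mm).
#' @param pulse_duration total pulse duration (s).
#' @param pulse_shape `"gaussian"` (default) or `"rectangular"`. See
#'   [pulse_profile()] for the exact definition.
#' @param entry_point beam entry point (mm, length 3), used by scene code.
#' @param direction unit vector of beam travel (length 3).
#' @return an object of class `beam_config`.
#' @export
beam_config <- function(energy = 100, n_protons = 5e6, sigma_lateral = 1,
                        pulse_duration = 10e-6, pulse_shape = c("gaussian", "rectangular"),
                        entry_point = c(0, 0, 0), direction = c(0, 0, 1)) {
  pulse_shape <- match.arg(pulse_shape)
  if (energy < 0) stop_domain("beam energy must be non-negative")
  if (energy < 80 || energy > 150)
    warning("beam energy ", energy, " MeV is outside the validated 80-150 MeV band")
  if (n_protons < 0) stop_domain("n_protons must be >= 0")
  if (sigma_lateral <= 0) stop_domain("sigma_lateral must be > 0")
  direction <- direction / sqrt(sum(direction^2))
  structure(list(energy = energy, n_protons = n_protons,
                 sigma_lateral = sigma_lateral, pulse_duration = pulse_duration,
                 pulse_shape = pulse_shape, entry_point = entry_point,
                 direction = direction),
            class = "beam_config")
}

#' Bone layer crossed by the beam
#'
#' Modelled as a pure water-equivalent range shift: traversing a layer of
#' thickness `thickness` with relative stopping power `rsp` pulls the Bragg
#' peak proximally by `thickness * (rsp - 1)`.
#'
#' @param thickness layer thickness (mm).
#' @param rsp relative stopping power (dimensionless, > 0).
#' @param position_along_beam depth (mm) at which the layer starts.
#' @return object of class `bone_layer`.
#' @export
bone_layer <- function(thickness = 10, rsp = 1.6, position_along_beam = 0) {
  if (thickness < 0) stop_domain("bone layer thickness must be >= 0")
  if (rsp <= 0) stop_domain("relative stopping power must be > 0")
  structure(list(thickness = thickness, rsp = rsp,
                 position_along_beam = position_along_beam),
            class = "bone_layer")
}

#' Bragg-Kleeman range in water
#'
#' `R = a * energy^p`, the continuous-slowing-down range of a proton in
#' water. Defaults `a = 0.022` mm MeV^-p, `p = 1.77` are the usual
#' Bragg-Kleeman water constants.
#'
#' @param energy proton energy (MeV), vectorized.
#' @param a,p Bragg-Kleeman constants.
#' @return range in mm.
#' @examples
#' bragg_range(100) # ~76.3 mm
#' @export
bragg_range <- function(energy, a = 0.022, p = 1.77) {
  if (any(energy < 0)) stop_domain("energy must be non-negative")
  a * energy^p
}

#' Per-proton depth-dose curve (Bragg curve)
#'
#' Analytic stand-in for a Monte Carlo depth-dose: the Bragg-Kleeman
#' differential curve `dE/dz = (R - z)^(1/p - 1) / (p a^(1/p))` convolved
#' with a Gaussian range-straggling kernel, then calibrated so that its
#' integral equals `energy * (1 - nuclear_loss)` (the configurable fraction
#' lost to non-local nuclear interactions).
#'
#' @param energy beam energy (MeV).
#' @param z depths (mm), a uniform increasing grid, `z >= 0`.
#' @param a,p Bragg-Kleeman constants (see [bragg_range()]).
#' @param straggle_frac range-straggling sigma as a fraction of the range.
#' @param nuclear_loss fraction of beam energy not deposited locally.
#' @return linear energy deposition per proton (MeV/mm) at each `z`.
#' @export
depth_dose <- function(energy, z, a = 0.022, p = 1.77,
                       straggle_frac = 0.01, nuclear_loss = 0.10) {
  if (any(z < 0)) stop_domain("depths must be non-negative")
  if (energy == 0) return(rep(0, length(z)))
  R <- bragg_range(energy, a, p)
  dz <- z[2] - z[1]
  u <- R - z
  raw <- ifelse(u > 0, u^(1 / p - 1), 0)
  sm <- gauss_smooth(raw, dz, straggle_frac * R)
  tot <- trapz(z, sm)
  if (tot <= 0) stop_domain("depth grid does not cover the deposition region")
  sm * (1 - nuclear_loss) * energy / tot
}

#' Voxelized dose grid
#'
#' Container for a deposited energy-density grid. `values` holds energy
#' density in J/m^3 on a cell-centred grid; the first voxel centre sits at
#' `origin`, axis `k` advancing by `spacing[k]` mm. `beam_axis` names the
#' axis along which the beam travels.
#'
#' @param values 3-d numeric array (J/m^3), all values `>= 0`.
#' @param origin centre of voxel `[1,1,1]` (mm, length 3).
#' @param spacing voxel pitch per axis (mm, length 1 or 3).
#' @param beam_axis index (1-3) of the beam axis.
#' @return object of class `dose_grid`.
#' @export
dose_grid <- function(values, origin = c(0, 0, 0), spacing = 1, beam_axis = 3L) {
  stopifnot(length(dim(values)) == 3)
  if (any(values < 0)) stop_domain("dose values must be non-negative")
  spacing <- rep(spacing, length.out = 3)
  structure(list(values = values, origin = origin, spacing = spacing,
                 beam_axis = as.integer(beam_axis)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  dV <- prod(x$spacing) * 1e-9
  cat("<dose_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(x$spacing, collapse = "/"), " mm\n",
      "  total deposited energy: ", format(sum(x$values) * dV, digits = 4), " J\n",
      sep = "")
  invisible(x)
}

# voxel centre coordinates along one axis
grid_axis <- function(grid, k) {
  grid$origin[k] + (seq_len(dim(grid$values)[k]) - 1) * grid$spacing[k]
}

#' Axial depth-dose profile of a grid
#'
#' Sums the grid over the two lateral axes, returning deposited energy (J)
#' per beam-axis slab together with slab-centre depths (mm, relative to the
#' grid origin along the beam axis).
#'
#' @param grid a [dose_grid()].
#' @return data.frame with columns `z_mm` and `energy_J`.
#' @export
axial_profile <- function(grid) {
  ax <- grid$beam_axis
  e <- apply(grid$values, ax, sum) * prod(grid$spacing) * 1e-9
  data.frame(z_mm = grid_axis(grid, ax), energy_J = e)
}

# water-equivalent depth for a bone layer spanning
# [position, position + thickness] along the beam
water_equivalent_depth <- function(z, bone) {
  if (is.null(bone)) return(z)
  overlap <- pmax(0, pmin(z, bone$position_along_beam + bone$thickness) -
                       bone$position_along_beam)
  z + (bone$rsp - 1) * overlap
}

#' Deposit a proton pulse on a 3-d grid
#'
#' Builds the deposited energy-density grid of one pulse: the analytic
#' depth-dose curve along the beam axis (z of the local frame) times a
#' lateral Gaussian with the beam's sigma, integrated exactly over each
#' voxel (error-function cell fractions laterally, fine sub-sampling
#' axially). With a [bone_layer()] present the axial coordinate is replaced
#' by its water-equivalent depth, shifting the peak proximally by
#' `thickness * (rsp - 1)`.
#'
#' @param beam a [beam_config()].
#' @param spacing voxel pitch (mm).
#' @param lateral_halfwidth lateral half-extent of the grid (mm); default
#'   covers +-4 sigma.
#' @param depth_margin extra depth beyond the range (mm).
#' @param bone optional [bone_layer()].
#' @param a,p,straggle_frac,nuclear_loss passed to [depth_dose()].
#' @param mode `"analytic"` (deterministic, default) or `"mc"`: Monte Carlo
#'   range straggling, sampling per-proton ranges from a Gaussian instead of
#'   convolving the curve.
#' @param n_mc number of sampled ranges in `"mc"` mode.
#' @param seed RNG seed for `"mc"` mode.
#' @return a [dose_grid()] in beam-local coordinates: beam travels along +z
#'   (axis 3) entering at z = 0, laterally centred on x = y = 0.
#' @export
deposit_3d <- function(beam, spacing = 1, lateral_halfwidth = NULL,
                       depth_margin = 8, bone = NULL,
                       a = 0.022, p = 1.77, straggle_frac = 0.01,
                       nuclear_loss = 0.10,
                       mode = c("analytic", "mc"), n_mc = 2000, seed = NULL) {
  mode <- match.arg(mode)
  R <- bragg_range(beam$energy, a, p)
  lateral_halfwidth <- lateral_halfwidth %||% max(4 * beam$sigma_lateral, 2 * spacing)
  depth <- R + depth_margin
  shift <- if (is.null(bone)) 0 else bone$thickness * (bone$rsp - 1)
  if (beam$energy > 0 && depth < (R - shift) * 0.999)
    stop_domain("grid depth ", depth, " mm does not contain the shifted range ",
                R - shift, " mm")

  # axial: energy per slab (MeV per proton), fine sub-sampling of the curve
  nz <- ceiling(depth / spacing)
  fine <- spacing / 20
  zf <- seq(fine / 2, nz * spacing, by = fine)
  if (beam$energy == 0) {
    slab <- rep(0, nz)
  } else if (mode == "analytic") {
    zeq <- water_equivalent_depth(zf, bone)
    # d(weq)/dz is rsp inside the layer: local deposition rate scales with it
    rate <- c(diff(zeq) / diff(zf), 1)
    ddz <- depth_dose_at(beam$energy, zeq, a, p, straggle_frac, nuclear_loss) * rate
    slab <- tapply(ddz * fine, rep(seq_len(nz), each = 20)[seq_along(zf)], sum)
  } else {
    if (!is.null(seed)) set.seed(seed)
    Rs <- stats::rnorm(n_mc, R, straggle_frac * R)
    slab <- numeric(nz)
    zeq <- water_equivalent_depth(zf, bone)
    rate <- c(diff(zeq) / diff(zf), 1)
    for (Ri in Rs) {
      u <- Ri - zeq
      raw <- ifelse(u > 0, u^(1 / p - 1), 0) / (p * a^(1 / p)) * rate
      slab <- slab + tapply(raw * fine, rep(seq_len(nz), each = 20)[seq_along(zf)], sum)
    }
    slab <- slab / n_mc
    slab <- slab * (1 - nuclear_loss) * beam$energy / sum(slab)
  }
  slab <- as.numeric(slab)

  # lateral: exact Gaussian cell fractions
  nxy <- 2 * ceiling(lateral_halfwidth / spacing)
  edges <- (seq_len(nxy + 1) - 1 - nxy / 2) * spacing
  fx <- diff(stats::pnorm(edges, 0, beam$sigma_lateral))

  vox_J <- outer(outer(fx, fx), slab) * beam$n_protons * MEV_J
  values <- vox_J / (prod(rep(spacing, 3)) * 1e-9) # J/m^3
  dose_grid(values,
            origin = c(edges[1] + spacing / 2, edges[1] + spacing / 2, spacing / 2),
            spacing = spacing, beam_axis = 3L)
}

# depth_dose evaluated at arbitrary (possibly non-uniform) depths via a fine
# uniform reference grid
depth_dose_at <- function(energy, z, a, p, straggle_frac, nuclear_loss) {
  R <- bragg_range(energy, a, p)
  zg <- seq(0, max(R * 1.2, max(z)) + 1, by = 0.01)
  dd <- depth_dose(energy, zg, a, p, straggle_frac, nuclear_loss)
  out <- stats::approx(zg, dd, xout = z, rule = 2)$y
  out
}

#' Bragg-peak region of a dose grid
#'
#' Selects all voxels with value at least `fraction` of the global maximum
#' and returns their energy-weighted centroid and bounding sphere.
#' On a uniform (constant) grid the whole grid is returned, its bounding
#' sphere spanning the grid diagonal; for a single above-threshold voxel the
#' diameter is the voxel size.
#'
#' @param grid a [dose_grid()].
#' @param fraction threshold as a fraction of the maximum, in (0, 1).
#' @return list with `centroid` (mm, grid coordinates), `diameter` (mm),
#'   `n_voxels`, `index` (matrix of voxel indices), `peak_value` (J/m^3) and
#'   `peak_depth` (mm along the beam axis: centre of the maximum voxel).
#' @export
peak_region <- function(grid, fraction = 0.5) {
  if (fraction <= 0 || fraction >= 1) stop_domain("fraction must be in (0, 1)")
  v <- grid$values
  mx <- max(v)
  if (mx <= 0) stop_domain("empty dose grid: no positive voxel")
  sel <- which(v >= fraction * mx, arr.ind = TRUE)
  ax <- lapply(1:3, function(k) grid_axis(grid, k))
  pts <- cbind(ax[[1]][sel[, 1]], ax[[2]][sel[, 2]], ax[[3]][sel[, 3]])
  w <- v[sel]
  centroid <- colSums(pts * w) / sum(w)
  rmax <- if (nrow(pts) > 1) max(sqrt(colSums((t(pts) - centroid)^2))) else 0
  diameter <- max(2 * rmax, min(grid$spacing))
  imax <- which(v == mx, arr.ind = TRUE)[1, ]
  list(centroid = centroid, diameter = diameter, n_voxels = nrow(pts),
       index = sel, peak_value = mx,
       peak_depth = ax[[grid$beam_axis]][imax[grid$beam_axis]])
}
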