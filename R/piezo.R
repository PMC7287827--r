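#' Piezoelectric disc geometry
#'
#' @param diameter disc diameter (mm).
#' @param thickness disc thickness (mm).
#' @param band allowed search band (mm); values outside warn.
#' @return object of class `disc_geometry`.
#' @export
disc_geometry <- function(diameter, thickness, band = c(5, 40)) {
  if (diameter <= 0 || thickness <= 0) stop_domain("disc dimensions must be > 0")
  if (diameter < band[1] || diameter > band[2] ||
      thickness < band[1] || thickness > band[2])
    warning("disc geometry outside the ", band[1], "-", band[2], " mm design band")
  structure(list(diameter = diameter, thickness = thickness),
            class = "disc_geometry")
}

#' Piezoceramic material constants
#'
#' Reduced scalar description of a piezoceramic for the analytic radial-mode
#' model: frequency constants (Hz m), coupling factors, and the Bessel-type
#' mode-shape constants of the first two radial modes. [pic255()] returns
#' the shipped PIC255 defaults (datasheet-derived).
#'
#' @param Np planar (radial) frequency constant, `fr1 * d` of a thin disc (Hz m).
#' @param Nt thickness frequency constant (Hz m).
#' @param N1 transverse (bar) frequency constant (Hz m); sets the
#'   radial/thickness coupled-mode correction `q = (Np/N1)^2`.
#' @param kp planar coupling factor of a thin disc.
#' @param kt thickness coupling factor.
#' @param k2p second-radial-mode coupling of a thin disc.
#' @param lambda1,lambda2 mode-shape constants of the first two radial modes
#'   (`lambda2 > lambda1`); only their ratio enters the model.
#' @param veering_A,veering_w depth and width (in aspect ratio) of the
#'   mode-veering suppression of the second-mode coupling where the
#'   thickness mode crosses the second radial mode.
#' @return object of class `piezo_material`.
#' @export
piezo_material <- function(Np, Nt, N1, kp, kt, k2p,
                           lambda1 = 2.05, lambda2 = 5.39,
                           veering_A = 0.75, veering_w = 0.25) {
  if (any(c(Np, Nt, N1, kp, kt, k2p, lambda1, lambda2) <= 0))
    stop_domain("material constants must be positive")
  if (lambda2 <= lambda1) stop_domain("need lambda2 > lambda1")
  structure(list(Np = Np, Nt = Nt, N1 = N1, kp = kp, kt = kt, k2p = k2p,
                 lambda1 = lambda1, lambda2 = lambda2,
                 veering_A = veering_A, veering_w = veering_w),
            class = "piezo_material")
}

#' @rdname piezo_material
#' @export
pic255 <- function() {
  piezo_material(Np = 2000, Nt = 2000, N1 = 1420,
                 kp = 0.62, kt = 0.47, k2p = 0.26)
}

# aspect ratio x = thickness/diameter where the thickness mode crosses the
# second radial mode: x / sqrt(1 + q x^2) = Nt / (r2 * Np)
veering_crossing <- function(material) {
  q <- (material$Np / material$N1)^2
  r2 <- material$lambda2 / material$lambda1
  s <- material$Nt / (r2 * material$Np)
  if (s^2 * q >= 1) return(Inf)
  s / sqrt(1 - s^2 * q)
}

# mode couplings as a function of aspect ratio
mode_couplings <- function(x, material) {
  q <- (material$Np / material$N1)^2
  k1 <- sqrt((material$kp^2 + material$kt^2 * q * x^2) / (1 + q * x^2))
  xs <- veering_crossing(material)
  w <- material$veering_w
  dip <- 1 - material$veering_A * w^2 / ((x - xs)^2 + w^2)
  k2 <- material$k2p * sqrt(dip) / sqrt(1 + q * x^2 / 4)
  list(k1 = k1, k2 = k2)
}

#' Radial resonance / anti-resonance pairs of a disc
#'
#' Analytic coupled-mode approximation of the first radial vibration modes:
#' \deqn{f_{r,n} = \frac{\lambda_n}{\lambda_1}\,\frac{N_p}{d}\,g_n(x), \qquad
#'   g_1(x) = (1 + q x^2)^{-1/2},\; g_2(x) = (1 + q x^2/4)^{-1/2},}
#' with aspect ratio `x = thickness/diameter` and `q = (Np/N1)^2` (the
#' empirical coupled radial/length resonator correction; `g(0) = 1`,
#' monotonically decreasing). Anti-resonances follow from the mode coupling
#' as `fa = fr / sqrt(1 - k^2)`. Aspect ratios above 1.5 are outside the
#' model's validity and flagged with a warning.
#'
#' @param geom a [disc_geometry()].
#' @param material a [piezo_material()].
#' @param n_modes 1 or 2.
#' @return list of `resonance_pair` objects: `list(fr, fa, mode, k)` (Hz).
#' @export
radial_resonances <- function(geom, material = pic255(), n_modes = 2) {
  if (!n_modes %in% 1:2) stop_domain("n_modes must be 1 or 2")
  x <- geom$thickness / geom$diameter
  if (x > 1.5) warning("aspect ratio thickness/diameter = ", round(x, 2),
                       " > 1.5: outside the radial-mode model validity band")
  q <- (material$Np / material$N1)^2
  d_m <- geom$diameter * 1e-3
  kk <- mode_couplings(x, material)
  ratios <- c(1, material$lambda2 / material$lambda1)
  g <- c(1 / sqrt(1 + q * x^2), 1 / sqrt(1 + q * x^2 / 4))
  ks <- c(kk$k1, kk$k2)
  lapply(seq_len(n_modes), function(n) {
    fr <- ratios[n] * material$Np / d_m * g[n]
    structure(list(fr = fr, fa = fr / sqrt(1 - ks[n]^2), mode = n, k = ks[n]),
              class = "resonance_pair")
  })
}

#' Electromechanical coupling coefficient
#'
#' IEEE definition from a resonance / anti-resonance pair:
#' `k = sqrt(1 - (fr/fa)^2)`.
#'
#' @param pair a `resonance_pair` (or any list with `fr`, `fa`).
#' @return coupling coefficient in `[0, 1)`.
#' @export
coupling_coefficient <- function(pair) {
  if (pair$fa < pair$fr || pair$fr <= 0) stop_domain("need fa >= fr > 0")
  sqrt(1 - (pair$fr / pair$fa)^2)
}

#' Grid-search disc geometry optimization
#'
#' Searches the (diameter, thickness) grid for the geometry whose
#' first-mode resonance band contains the target frequency
#' (`fr1 <= target <= fa1`) and maximizes the coupling ratio `k1/k2`
#' (energy preferentially in the fundamental radial mode over the second).
#' Aspect ratios above 1.5 are excluded as outside model validity. Ties are
#' broken toward the smaller diameter, then the smaller thickness. The
#' search is deterministic.
#'
#' @param target_freq target central frequency (Hz).
#' @param material a [piezo_material()].
#' @param grid_step grid pitch (mm).
#' @param band search band (mm).
#' @return list with `geometry` (a [disc_geometry()]), `score` (k1/k2),
#'   `fr1`, `fa1`, and `surface`: a data.frame over the full grid with
#'   columns `diameter`, `thickness`, `fr1`, `fa1`, `fr2`, `fa2`, `k1`,
#'   `k2`, `score`, `feasible`.
#' @export
optimize_geometry <- function(target_freq, material = pic255(), grid_step = 1,
                              band = c(5, 40)) {
  ds <- seq(band[1], band[2], by = grid_step)
  ths <- seq(band[1], band[2], by = grid_step)
  g <- expand.grid(diameter = ds, thickness = ths)
  x <- g$thickness / g$diameter
  q <- (material$Np / material$N1)^2
  d_m <- g$diameter * 1e-3
  r2 <- material$lambda2 / material$lambda1
  kk <- mode_couplings(x, material)
  fr1 <- material$Np / d_m / sqrt(1 + q * x^2)
  fr2 <- r2 * material$Np / d_m / sqrt(1 + q * x^2 / 4)
  fa1 <- fr1 / sqrt(1 - kk$k1^2)
  fa2 <- fr2 / sqrt(1 - kk$k2^2)
  score <- kk$k1 / kk$k2
  feasible <- fr1 <= target_freq & target_freq <= fa1 & x <= 1.5
  surface <- data.frame(diameter = g$diameter, thickness = g$thickness,
                        fr1 = fr1, fa1 = fa1, fr2 = fr2, fa2 = fa2,
                        k1 = kk$k1, k2 = kk$k2, score = score,
                        feasible = feasible)
  if (!any(feasible)) {
    i <- which.min(pmax(fr1 - target_freq, target_freq - fa1))
    stop_domain("no feasible geometry for ", target_freq, " Hz; nearest: d = ",
                g$diameter[i], " mm, th = ", g$thickness[i], " mm (fr1 = ",
                round(fr1[i]), " Hz, fa1 = ", round(fa1[i]), " Hz)")
  }
  cand <- which(feasible)
  best <- cand[order(-score[cand], g$diameter[cand], g$thickness[cand])][1]
  list(geometry = disc_geometry(g$diameter[best], g$thickness[best]),
       score = score[best], fr1 = fr1[best], fa1 = fa1[best],
       surface = surface)
}
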