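# Independent oracles used by the tests. These deliberately avoid the
# package's retarded-time/binning code paths: closed forms and brute-force
# arithmetic only.

# Closed-form thermoacoustic pressure of a point source with total energy
# eps_J (J) at distance d_mm from the observer. With the separable source
# eps(r) * S_cum(t), the second time derivative of the deposited density is
# the first derivative of the pulse profile S:
#   p(t) = alpha/(4 pi Cp) * (eps dV / d) * S'(t - d/cs).
# The package's gaussian profile is the edge-corrected truncated gaussian
# (mean duration/2, sigma = duration/6, shifted to zero at the edges and
# renormalized); its derivative in closed form is used here.
point_source_oracle <- function(t, eps_J, d_mm, medium, pulse) {
  stopifnot(pulse$shape == "gaussian")
  mu <- pulse$duration / 2
  sg <- pulse$duration / 6
  c0 <- stats::dnorm(0, mu, sg)
  A <- (stats::pnorm(pulse$duration, mu, sg) - stats::pnorm(0, mu, sg)) -
    c0 * pulse$duration
  tr <- t - d_mm * 1e-3 / medium$cs
  inside <- tr >= 0 & tr <= pulse$duration
  S1 <- ifelse(inside, -(tr - mu) / sg^2 * stats::dnorm(tr, mu, sg) / A, 0)
  medium$alpha_thermal / (4 * pi * medium$Cp) * (eps_J / (d_mm * 1e-3)) * S1
}

# brute-force superposition of point sources over every positive voxel of a
# dose grid (voxel centres, no subdivision)
superposition_oracle <- function(t, grid, obs, medium, pulse) {
  idx <- which(grid$values > 0, arr.ind = TRUE)
  axl <- lapply(1:3, function(k)
    grid$origin[k] + (seq_len(dim(grid$values)[k]) - 1) * grid$spacing[k])
  p <- numeric(length(t))
  dV <- prod(grid$spacing) * 1e-9
  vals <- grid$values[idx]
  for (r in seq_len(nrow(idx))) {
    pt <- c(axl[[1]][idx[r, 1]], axl[[2]][idx[r, 2]], axl[[3]][idx[r, 3]])
    d <- sqrt(sum((pt - obs)^2))
    p <- p + point_source_oracle(t, vals[r] * dV, d, medium, pulse)
  }
  p
}

# exact geometric TOAs (s) of a source seen by a sensor matrix, all-fluid
exact_toas <- function(source, positions, c_sound = 1500) {
  sqrt(colSums((t(positions) - source)^2)) * 1e-3 / c_sound
}

# small dose grid with seeded random voxel values (J/m^3)
random_grid <- function(n = 3, spacing = 1, seed = 42) {
  set.seed(seed)
  dose_grid(array(stats::runif(n^3, 0, 500), dim = c(n, n, n)),
            origin = c(0, 0, 0), spacing = spacing)
}

# RMS helper
rms <- function(x) sqrt(mean(x^2))
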