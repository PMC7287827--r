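# Internal constants and small numeric helpers.
#
# Unit conventions used throughout the package:
#   positions / lengths  mm          times      s
#   speeds               m/s         pressure   Pa
#   energy density       J/m^3       beam energy MeV

MEV_J <- 1.602176634e-13 # J per MeV

# trapezoidal integral of y(x) on an (increasing) grid
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

# gaussian smoothing of a uniformly sampled curve, reflecting nothing
# (zero-padded); kernel truncated at 4 sigma and renormalized
gauss_smooth <- function(y, dx, sigma) {
  if (sigma <= 0) return(y)
  half <- max(1L, ceiling(4 * sigma / dx))
  k <- stats::dnorm((-half:half) * dx, 0, sigma)
  k <- k / sum(k)
  n <- length(y)
  padded <- c(rep(0, half), y, rep(0, half))
  out <- stats::filter(padded, k, sides = 2)[(half + 1):(half + n)]
  out[is.na(out)] <- 0
  as.numeric(out)
}
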