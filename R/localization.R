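#' Sensor array
#'
#' At least four sensors are required for a 3-D fix from time differences of
#' arrival; with fewer the constructor refuses. Near-coplanar arrays (such
#' as the shipped six-sensor head geometry, whose sensors share almost the
#' same axial plane) are accepted with a conditioning warning: the fix is
#' unique but ill-conditioned along the array normal.
#'
#' @param positions numeric matrix, one row per sensor (mm, 3 columns).
#' @param labels optional sensor labels.
#' @return object of class `sensor_array`.
#' @export
sensor_array <- function(positions, labels = NULL) {
  positions <- rbind(positions)
  if (nrow(positions) < 4)
    stop_domain("a minimum of 4 sensors is needed for a 3-D TDOA fix (got ",
                nrow(positions), ")")
  if (ncol(positions) != 3) stop_domain("positions must have 3 columns")
  ctr <- colMeans(positions)
  sv <- svd(sweep(positions, 2, ctr))$d
  if (sv[3] < 1e-9 * sv[1])
    warning("sensor positions are coplanar: the TDOA fix is not unique")
  else if (sv[3] < 0.05 * sv[1])
    warning("sensor array is nearly coplanar: reconstruction is ",
            "ill-conditioned along the array normal")
  labels <- labels %||% paste0("S", seq_len(nrow(positions)))
  structure(list(positions = positions, labels = labels), class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat("<sensor_array> ", nrow(x$positions), " sensors\n", sep = "")
  print(data.frame(label = x$labels, x = x$positions[, 1],
                   y = x$positions[, 2], z = x$positions[, 3]))
  invisible(x)
}

#' Time of arrival by cross-correlation
#'
#' Lag maximizing the normalized cross-correlation between a received trace
#' and the emitted-signal template, refined to sub-sample precision by
#' parabolic interpolation of the correlation peak. If the peak correlation
#' coefficient falls below `min_corr` the estimate is flagged unreliable
#' (returned as `NA` with a warning).
#'
#' @param trace a [pressure_trace()] (the received signal).
#' @param template a [pressure_trace()] with the same `dt`, not longer than
#'   `trace`.
#' @param min_corr significance threshold on the normalized peak coefficient.
#' @return lag (s) of the trace relative to the template, with the peak
#'   normalized correlation as attribute `"corr"`.
#' @export
estimate_toa <- function(trace, template, min_corr = 0.2) {
  if (abs(trace$dt - template$dt) > 1e-15 * trace$dt)
    stop_domain("trace and template must share the sampling step")
  if (length(template$p) > length(trace$p))
    stop_domain("template must not be longer than the trace")
  x <- trace$p
  y <- template$p
  if (max(abs(x)) == 0) stop_domain("flat trace: no arrival to estimate")
  # cross-correlation: convolve(x, y, conj = TRUE) gives sum x[k+j] y[j]
  cc <- stats::convolve(x, y, conj = TRUE, type = "open")
  k <- which.max(cc)
  denom <- sqrt(sum(x^2) * sum(y^2))
  rho <- cc[k] / denom
  if (rho < min_corr) {
    warning("correlation peak ", round(rho, 3), " below significance threshold ",
            min_corr, "; TOA flagged unreliable")
    return(structure(NA_real_, corr = rho))
  }
  delta <- 0
  if (k > 1 && k < length(cc)) {
    y1 <- cc[k - 1]; y2 <- cc[k]; y3 <- cc[k + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) delta <- 0.5 * (y1 - y3) / den
  }
  structure((k + delta - length(y)) * trace$dt, corr = rho)
}

#' Apply an arrival-time correction
#'
#' Subtracts the layer-induced arrival-time shift from measured TOAs so the
#' corrected times correspond to an all-fluid path (which is what the TDOA
#' solver assumes). `correction` is either a single value (constant mode; it
#' cancels in the time differences) or one value per sensor (per-path mode).
#' The skull layer makes arrivals earlier, so its shift is negative:
#' `-toa_correction(...)` per sensor.
#'
#' @param toas measured arrival times or correlation lags (s).
#' @param correction scalar or per-sensor vector (s).
#' @return corrected times (s).
#' @export
correct_toas <- function(toas, correction) {
  if (!length(correction) %in% c(1L, length(toas)))
    stop_domain("correction must be scalar or one value per sensor")
  toas - correction
}

#' Time-difference-of-arrival set
#'
#' @param toas arrival times (s), one per sensor.
#' @param ref reference sensor index.
#' @param c_sound speed of sound used for the solve (m/s).
#' @return object of class `tdoa_set` with `dt` (s, `dt[ref] == 0`).
#' @export
tdoa_set <- function(toas, ref = 1L, c_sound = 1500) {
  if (any(!is.finite(toas))) stop_domain("non-finite TOA in the set")
  structure(list(dt = toas - toas[ref], ref = as.integer(ref),
                 c_sound = c_sound), class = "tdoa_set")
}

# residuals (mm) of the TDOA system at position x
tdoa_residual <- function(x, positions, tdoas) {
  r <- sqrt(colSums((t(positions) - x)^2))
  (r - r[tdoas$ref]) - tdoas$dt * tdoas$c_sound * 1e3
}

#' Solve the TDOA system for the source position
#'
#' Solves the hyperbolic multilateration system
#' \eqn{F_i(x) = |x - s_i| - |x - s_{ref}| - c\,\Delta t_i = 0}
#' in the least-squares sense by damped Gauss-Newton (Levenberg-style
#' diagonal regularization plus Armijo backtracking line search) — a robust
#' Newton-type iteration that converges from any start in the search box.
#' On non-convergence the solve restarts from the 8 corners and the centroid
#' of the box and keeps the best result.
#'
#' @param array a [sensor_array()].
#' @param tdoas a [tdoa_set()].
#' @param init starting point (mm) or `NULL` for the box centre.
#' @param box search box as a 2 x 3 matrix (rows: lower, upper, mm); default
#'   is the sensor bounding box expanded by 20 mm.
#' @param tol step-norm convergence tolerance (mm).
#' @param max_iter maximum iterations per start.
#' @return object of class `reconstruction_result`: `position` (mm),
#'   `residual_norm` (mm, RMS), `iterations`, `converged`, and the
#'   per-sensor `predicted_dt` vs `measured_dt` (s).
#' @export
solve_position <- function(array, tdoas, init = NULL, box = NULL,
                           tol = 1e-9, max_iter = 100) {
  positions <- array$positions
  if (nrow(positions) - 1 < 3)
    stop_domain("under-determined: need at least 3 independent TDOA equations")
  box <- box %||% rbind(apply(positions, 2, min) - 20,
                        apply(positions, 2, max) + 20)
  starts <- list(init %||% colMeans(box))
  gn <- function(x0) {
    x <- x0
    it <- 0
    for (it in seq_len(max_iter)) {
      F0 <- tdoa_residual(x, positions, tdoas)
      r <- sqrt(colSums((t(positions) - x)^2))
      J <- t(vapply(seq_len(nrow(positions)), function(i)
        (x - positions[i, ]) / r[i], numeric(3)))
      J <- J[-tdoas$ref, , drop = FALSE] -
        matrix(J[tdoas$ref, ], nrow(J) - 1, 3, byrow = TRUE)
      Fv <- F0[-tdoas$ref]
      A <- crossprod(J)
      dx <- tryCatch(
        as.numeric(solve(A + 1e-10 * max(diag(A), 1e-300) * diag(3),
                         -crossprod(J, Fv))),
        error = function(e) -as.numeric(crossprod(J, Fv)))
      f0 <- sum(Fv^2)
      s <- 1
      repeat {
        Ft <- tdoa_residual(x + s * dx, positions, tdoas)[-tdoas$ref]
        if (sum(Ft^2) <= f0 * (1 - 1e-4 * s) || s < 1e-8) break
        s <- s / 2
      }
      x <- x + s * dx
      if (sqrt(sum((s * dx)^2)) < tol) break
    }
    Ff <- tdoa_residual(x, positions, tdoas)[-tdoas$ref]
    list(x = x, rms = sqrt(mean(Ff^2)), it = it,
         conv = sqrt(mean(Ff^2)) < 1e-6 || sqrt(sum((s * dx)^2)) < tol)
  }
  res <- gn(starts[[1]])
  if (!res$conv) {
    corners <- as.matrix(expand.grid(box[, 1], box[, 2], box[, 3]))
    for (i in seq_len(nrow(corners))) {
      alt <- gn(corners[i, ])
      if (alt$rms < res$rms) res <- alt
    }
  }
  r <- sqrt(colSums((t(positions) - res$x)^2))
  structure(list(position = res$x, residual_norm = res$rms,
                 iterations = res$it, converged = res$conv,
                 predicted_dt = (r - r[tdoas$ref]) * 1e-3 / tdoas$c_sound,
                 measured_dt = tdoas$dt),
            class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat("<reconstruction_result>\n  position: (",
      paste(sprintf("%.2f", x$position), collapse = ", "), ") mm\n",
      "  residual RMS: ", format(x$residual_norm, digits = 3), " mm in ",
      x$iterations, " iterations (converged: ", x$converged, ")\n", sep = "")
  invisible(x)
}

#' Euclidean localization error
#'
#' @param result a [solve_position()] result (or a length-3 position).
#' @param true_position the true source position (mm).
#' @return Euclidean distance (mm).
#' @export
localization_error <- function(result, true_position) {
  pos <- if (inherits(result, "reconstruction_result")) result$position else result
  sqrt(sum((pos - true_position)^2))
}
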