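#' Trace, grid and scene file I/O
#'
#' All formats are plain text: delimited tables for the numeric payloads and
#' a JSON sidecar (same path plus `.json`) holding the metadata needed to
#' reconstruct the object.
#'
#' @name protoacoustics-io
NULL

#' @describeIn protoacoustics-io write a [pressure_trace()] as a two-column
#'   (t_s, p_Pa) tab-separated file with a JSON sidecar.
#' @param trace a [pressure_trace()].
#' @param path output file path.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(data.frame(t_s = trace$t, p_Pa = trace$p), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(dt = trace$dt,
                            observation_point = trace$observation_point,
                            units = list(t = "s", p = "Pa")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @describeIn protoacoustics-io read a trace written by [write_trace()].
#' @export
read_trace <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pressure_trace(d$t_s, d$p_Pa,
                 observation_point = as.numeric(meta$observation_point))
}

#' @describeIn protoacoustics-io write a [dose_grid()] as a flat value file
#'   (one voxel per line, column-major order) plus a JSON sidecar with
#'   origin, spacing, shape and units.
#' @param grid a [dose_grid()].
#' @export
write_dose_grid <- function(grid, path) {
  writeLines(format(as.numeric(grid$values), digits = 10, trim = TRUE,
                    scientific = TRUE), path)
  jsonlite::write_json(list(origin = grid$origin, spacing = grid$spacing,
                            shape = dim(grid$values),
                            beam_axis = grid$beam_axis,
                            order = "column-major",
                            units = list(values = "J/m^3", lengths = "mm")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @describeIn protoacoustics-io read a grid written by [write_dose_grid()].
#' @export
read_dose_grid <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- array(as.numeric(readLines(path)), dim = meta$shape)
  dose_grid(v, origin = meta$origin, spacing = meta$spacing,
            beam_axis = meta$beam_axis)
}

#' @describeIn protoacoustics-io export the axial depth-dose curve of a grid
#'   as a comma-separated table (z_mm, dose_J).
#' @export
export_depth_dose <- function(grid, path) {
  utils::write.csv(axial_profile(grid), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn protoacoustics-io read a sensor-array JSON file: a list of
#'   objects `{label, x_mm, y_mm, z_mm}`.
#' @export
read_sensors <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  suppressWarnings(sensor_array(cbind(d$x_mm, d$y_mm, d$z_mm), d$label))
}

#' @describeIn protoacoustics-io serialize a [layered_scene()] to JSON.
#' @param scene a [layered_scene()].
#' @export
write_scene <- function(scene, path) {
  s <- scene
  obj <- list(
    sensors = data.frame(label = s$sensors$labels,
                         x_mm = s$sensors$positions[, 1],
                         y_mm = s$sensors$positions[, 2],
                         z_mm = s$sensors$positions[, 3]),
    beam = unclass(s$beam), medium = unclass(s$medium),
    interface = unclass(s$iface),
    skull_center = s$skull_center,
    skull_outer_radius = s$skull_outer_radius,
    source_target = s$source_target,
    source_diameter = s$source_diameter,
    template_distance = s$template_distance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @describeIn protoacoustics-io read a scene written by [write_scene()].
#' @export
read_scene <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  layered_scene(
    sensors = suppressWarnings(sensor_array(
      cbind(o$sensors$x_mm, o$sensors$y_mm, o$sensors$z_mm), o$sensors$label)),
    beam = beam_config(o$beam$energy, o$beam$n_protons, o$beam$sigma_lateral,
                       o$beam$pulse_duration, o$beam$pulse_shape,
                       as.numeric(o$beam$entry_point),
                       as.numeric(o$beam$direction)),
    medium = acoustic_medium(o$medium$cs, o$medium$Cp, o$medium$alpha_thermal,
                             o$medium$rho, o$medium$alpha_atten),
    iface = fluid_solid_interface(o$interface$c_fluid, o$interface$c_long,
                                  o$interface$c_shear, o$interface$rho_fluid,
                                  o$interface$rho_solid,
                                  o$interface$layer_thickness),
    skull_center = as.numeric(o$skull_center),
    skull_outer_radius = o$skull_outer_radius,
    source_target = as.numeric(o$source_target),
    source_diameter = o$source_diameter,
    template_distance = o$template_distance)
}
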