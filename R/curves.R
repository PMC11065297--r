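#' Aspiration depth-versus-time curve
#'
#' The fit target of the creep model: aspiration depth of the zona pellucida
#' inside the micropipette, in micrometers relative to the pipette tip plane,
#' sampled at the camera frame times of the clipped recording.
#'
#' @param times Seconds from clip start; strictly increasing, starting at 0.
#' @param depths Depths in micrometers, `>= 0`.
#' @param frame_rate Acquisition frame rate in Hz.
#' @param zona_thickness Zona pellucida thickness in micrometers, if measured.
#' @param pipette_inner_diameter Pipette inner diameter in micrometers.
#' @param conversion_factor Micrometers per pixel used to scale the depths.
#' @return An object of class `aspiration_curve`.
#' @export
aspiration_curve <- function(times, depths, frame_rate = NA_real_,
                             zona_thickness = NA_real_,
                             pipette_inner_diameter = NA_real_,
                             conversion_factor = NA_real_) {
  times <- as.numeric(times)
  depths <- as.numeric(depths)
  if (length(times) != length(depths)) {
    stop_oomech("times and depths must have equal length", "oomech_invalid_input")
  }
  if (length(times) == 0L || times[1] != 0 || any(diff(times) <= 0)) {
    stop_oomech("times must start at 0 and be strictly increasing",
                "oomech_invalid_input")
  }
  if (any(depths < 0)) {
    stop_oomech("depths must be non-negative", "oomech_invalid_input")
  }
  if (!is.na(conversion_factor) && conversion_factor <= 0) {
    stop_oomech("conversion_factor must be positive", "oomech_invalid_input")
  }
  structure(
    list(times = times, depths = depths, frame_rate = frame_rate,
         zona_thickness = zona_thickness,
         pipette_inner_diameter = pipette_inner_diameter,
         conversion_factor = conversion_factor),
    class = "aspiration_curve"
  )
}

#' @export
print.aspiration_curve <- function(x, ...) {
  cat(sprintf("Aspiration curve: %d samples over %.3f s, depth %.2f-%.2f um\n",
              length(x$times), max(x$times), min(x$depths), max(x$depths)))
  invisible(x)
}

#' @export
as.data.frame.aspiration_curve <- function(x, ...) {
  data.frame(time_s = x$times, depth_um = x$depths)
}

#' Recorded suction pressure trace
#'
#' Pressure log of one measurement: the instrument records pressure in
#' p.s.i., with suction as values below the balance pressure (typically
#' negative), before and during the aspiration.
#'
#' @param times Sample times in seconds, non-negative, strictly increasing.
#' @param pressures Recorded pressures in p.s.i. (suction negative).
#' @param balance_pressure Balance (resting) pressure in p.s.i.
#' @return An object of class `pressure_trace`.
#' @export
pressure_trace <- function(times, pressures, balance_pressure = 0) {
  times <- as.numeric(times)
  pressures <- as.numeric(pressures)
  if (length(times) != length(pressures) || length(times) < 1L) {
    stop_oomech("times and pressures must be non-empty and of equal length",
                "oomech_invalid_input")
  }
  if (any(times < 0) || any(diff(times) <= 0)) {
    stop_oomech("times must be non-negative and strictly increasing",
                "oomech_invalid_input")
  }
  if (all(pressures >= balance_pressure)) {
    stop_oomech("trace records no suction below the balance pressure",
                "oomech_invalid_input")
  }
  structure(
    list(times = times, pressures = pressures,
         balance_pressure = balance_pressure),
    class = "pressure_trace"
  )
}

#' Write / read aspiration curves as CSV
#'
#' One row per frame with columns `oocyte_id`, `time_s`, `depth_um`; curve
#' metadata travels in extra constant columns.
#'
#' @param curves Named list of [aspiration_curve()] objects (names are
#'   oocyte ids).
#' @param path CSV file path.
#' @return `write_curves_csv()` returns `path` invisibly; `read_curves_csv()`
#'   returns a named list of curves.
#' @export
write_curves_csv <- function(curves, path) {
  stopifnot(is.list(curves), !is.null(names(curves)))
  rows <- lapply(names(curves), function(id) {
    cv <- curves[[id]]
    data.frame(oocyte_id = id, time_s = cv$times, depth_um = cv$depths,
               frame_rate = cv$frame_rate,
               zona_thickness_um = cv$zona_thickness,
               pipette_inner_diameter_um = cv$pipette_inner_diameter,
               conversion_factor = cv$conversion_factor)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves_csv
#' @export
read_curves_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$oocyte_id), function(g) {
    g <- g[order(g$time_s), ]
    aspiration_curve(g$time_s, g$depth_um, frame_rate = g$frame_rate[1],
                     zona_thickness = g$zona_thickness_um[1],
                     pipette_inner_diameter = g$pipette_inner_diameter_um[1],
                     conversion_factor = g$conversion_factor[1])
  })
  out[unique(df$oocyte_id)]
}

#' Write / read pressure traces as CSV
#'
#' Columns `time_s`, `pressure_psi`; the balance pressure is stored as a
#' constant `balance_psi` column.
#'
#' @param trace A [pressure_trace()].
#' @param path CSV file path.
#' @export
write_pressure_csv <- function(trace, path) {
  utils::write.csv(
    data.frame(time_s = trace$times, pressure_psi = trace$pressures,
               balance_psi = trace$balance_pressure),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pressure_csv
#' @export
read_pressure_csv <- function(path) {
  df <- utils::read.csv(path)
  pressure_trace(df$time_s, df$pressure_psi, balance_pressure = df$balance_psi[1])
}
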