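# Schematic renderer of aspiration recordings. Emulates the measurement
# geometry (oocyte pressed against a horizontal pipette, zona tongue drawn
# into the lumen) well enough to benchmark the tracker against ground truth;
# it is not a photorealistic microscopy simulator.

#' Ordered grayscale frame stack
#'
#' @param frames List of equally sized numeric matrices with values in
#'   `[0, 1]` (rows = y, columns = x).
#' @param frame_rate Frames per second.
#' @param um_per_px Micrometers per pixel, or `NA` if unknown (then derived
#'   from the pipette inner diameter at tracking time).
#' @param truth Optional ground-truth `data.frame` (synthetic stacks only).
#' @param onset Optional ground-truth index of the first moved frame.
#' @param geometry Optional list of rendering geometry.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate, um_per_px = NA_real_,
                        truth = NULL, onset = NA_integer_, geometry = NULL) {
  if (!is.list(frames) || length(frames) < 2L) {
    stop_oomech("a frame stack needs at least 2 frames", "oomech_invalid_input")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_oomech("all frames must share one shape", "oomech_invalid_input")
  }
  check_positive(frame_rate, "frame_rate")
  structure(
    list(frames = frames, frame_rate = frame_rate, um_per_px = um_per_px,
         truth = truth, onset = onset, geometry = geometry),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Frame stack: %d frames of %dx%d px at %g fps (%g um/px)\n",
              length(x$frames), d[1], d[2], x$frame_rate, x$um_per_px))
  invisible(x)
}

#' Render an aspiration recording from a depth curve
#'
#' Draws, per frame: the oocyte body with its bright zona pellucida annulus
#' pressed against the pipette mouth, the pipette walls, and the aspirated
#' zona tongue inside the lumen. The tongue tip sits at
#' `zona_thickness + depth` micrometers from the tip plane (at rest the
#' inner zona boundary lies one zona thickness inside the mouth, which is
#' why the zona thickness serves as the initial aspiration depth); the tip
#' edge is anti-aliased so sub-pixel tracking is meaningful. `n_lead` static
#' frames precede suction onset.
#'
#' @param curve An [aspiration_curve()] of depths beyond the resting
#'   position.
#' @param um_per_px Micrometers per pixel.
#' @param image_shape `c(rows, cols)` of each frame.
#' @param oocyte_diameter,pipette_inner_diameter,zona_thickness,wall_thickness
#'   Geometry in micrometers.
#' @param n_lead Number of pre-suction static frames.
#' @param noise_sd Gaussian pixel noise (intensity units).
#' @param seed Optional seed for the pixel noise.
#' @return A [frame_stack()] whose `truth` holds per-frame tip positions
#'   (px and um from the tip plane) and whose `onset` is the index of the
#'   first moved frame.
#' @export
render_frame_stack <- function(curve, um_per_px = 0.5,
                               image_shape = c(160L, 280L),
                               oocyte_diameter = 110,
                               pipette_inner_diameter = 50,
                               zona_thickness = 15, wall_thickness = 4,
                               n_lead = 5L, noise_sd = 0.02, seed = NULL) {
  stopifnot(inherits(curve, "aspiration_curve"))
  check_positive(um_per_px, "um_per_px")
  ny <- image_shape[1]; nx <- image_shape[2]
  lumen_len_px <- round(0.45 * nx)
  x_tip <- nx - lumen_len_px
  cy <- ny / 2
  r_lumen <- pipette_inner_diameter / 2 / um_per_px
  r_wall <- r_lumen + wall_thickness / um_per_px
  R_out <- oocyte_diameter / 2 / um_per_px
  R_in <- R_out - zona_thickness / um_per_px
  zt_px <- zona_thickness / um_per_px

  tip_um <- c(rep(zona_thickness, n_lead), zona_thickness + curve$depths)
  tip_px <- tip_um / um_per_px
  if (max(tip_px) > lumen_len_px - 4) {
    stop_oomech("aspiration depth exceeds the rendered pipette length",
                "oomech_geometry_error")
  }

  bg <- 0.10; body <- 0.45; zona <- 0.90; wall <- 0.80
  xs <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  ys <- matrix(seq_len(ny), ny, nx)
  rr <- sqrt((xs - (x_tip - R_out))^2 + (ys - cy)^2)
  base <- matrix(bg, ny, nx)
  base[rr < R_in] <- body
  base[rr >= R_in & rr <= R_out & xs <= x_tip] <- zona
  in_wall <- xs >= x_tip & abs(ys - cy) > r_lumen & abs(ys - cy) <= r_wall
  base[in_wall] <- wall
  in_lumen <- xs > x_tip & abs(ys - cy) <= r_lumen

  noise <- with_seed(seed, stats::rnorm(ny * nx * length(tip_px), 0, noise_sd))
  if (noise_sd == 0) noise <- rep(0, ny * nx * length(tip_px))

  frames <- lapply(seq_along(tip_px), function(k) {
    f <- base
    # anti-aliased tongue: full columns up to floor(tip), fractional last one
    cov <- pmin(pmax(tip_px[k] - (xs - x_tip - 1), 0), 1)
    tongue <- in_lumen & cov > 0
    f[tongue] <- bg + (zona - bg) * cov[tongue]
    f <- f + noise[((k - 1) * ny * nx + 1):(k * ny * nx)]
    pmin(pmax(f, 0), 1)
  })

  frame_stack(
    frames, frame_rate = curve$frame_rate, um_per_px = um_per_px,
    truth = data.frame(frame = seq_along(tip_px), tip_px = tip_px,
                       tip_um = tip_um,
                       depth_um = tip_um - zona_thickness),
    onset = n_lead + 1L,
    geometry = list(x_tip = x_tip, cy = cy, r_lumen_px = r_lumen,
                    zona_thickness_um = zona_thickness,
                    pipette_inner_diameter_um = pipette_inner_diameter,
                    oocyte_diameter_um = oocyte_diameter,
                    n_lead = n_lead)
  )
}

#' Write / read a frame stack as PNG files plus a JSON sidecar
#'
#' Frames go to zero-padded `frame_0001.png` files; acquisition metadata,
#' geometry and any ground truth go to `stack.json`.
#'
#' @param stack A [frame_stack()].
#' @param dir Output directory (created if needed).
#' @export
write_frame_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(stack$frames)) {
    png::writePNG(stack$frames[[k]],
                  file.path(dir, sprintf("frame_%04d.png", k)))
  }
  meta <- list(frame_rate = stack$frame_rate, um_per_px = stack$um_per_px,
               onset = stack$onset, geometry = stack$geometry,
               truth = stack$truth)
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) < 2L) {
    stop_oomech("no frame PNGs found in directory", "oomech_invalid_input")
  }
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  })
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  frame_stack(frames, frame_rate = meta$frame_rate,
              um_per_px = meta$um_per_px,
              truth = meta$truth,
              onset = if (is.null(meta$onset)) NA_integer_ else meta$onset,
              geometry = meta$geometry)
}
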