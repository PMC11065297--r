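# Video analysis: from a grayscale frame stack to an aspiration
# depth-vs-time curve in micrometers. The pipette is assumed horizontal
# with its mouth opening to the left (use rotate_stack() first otherwise);
# all boundaries are found automatically from intensity profiles, with
# positions_from_labels() as the fallback for manually labelled frames.

normalize_frame <- function(f) {
  rng <- range(f)
  if (diff(rng) < 1e-6) {
    stop_oomech("frame has no contrast; boundaries cannot be detected",
                "oomech_detection_error")
  }
  (f - rng[1]) / diff(rng)
}

# Locate the pipette in a frame: wall rows from the rightmost columns, the
# lumen centerline and half-width from the gap between walls, and the tip
# plane by walking the wall band leftwards until it ends.
detect_pipette <- function(frame) {
  f <- normalize_frame(frame)
  ny <- nrow(f); nx <- ncol(f)
  vprof <- rowMeans(f[, (nx - 2):nx, drop = FALSE])
  bright <- vprof > 0.5
  runs <- rle(bright)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  wall_idx <- which(runs$values & runs$lengths >= 2)
  if (length(wall_idx) < 2L) {
    stop_oomech("pipette walls not detected", "oomech_detection_error")
  }
  # the two wall bands flanking the widest dark gap
  gaps <- which(!runs$values)
  gaps <- gaps[gaps > min(wall_idx) & gaps < max(wall_idx)]
  if (length(gaps) == 0L) {
    stop_oomech("pipette lumen not detected", "oomech_detection_error")
  }
  lumen <- gaps[which.max(runs$lengths[gaps])]
  upper <- max(wall_idx[wall_idx < lumen])
  lower <- min(wall_idx[wall_idx > lumen])
  lumen_top <- starts[lumen]; lumen_bot <- ends[lumen]
  cy <- (lumen_top + lumen_bot) / 2
  wall_row <- round((starts[upper] + ends[upper]) / 2)
  # walk the wall band right-to-left; the tip plane is where it stops
  wvals <- f[wall_row, ]
  dark <- which(wvals < 0.5)
  dark <- dark[dark < nx - 2]
  x_tip <- if (length(dark) == 0L) 1L else max(dark) + 1L
  list(x_tip = x_tip, cy = cy, lumen_top = lumen_top, lumen_bot = lumen_bot,
       half_width = (lumen_bot - lumen_top + 1) / 2)
}

#' Crop a region of interest out of every frame
#'
#' @param stack A [frame_stack()].
#' @param roi Integer vector `c(row_min, row_max, col_min, col_max)`
#'   (1-based, inclusive).
#' @return A [frame_stack()] of cropped frames with geometry metadata
#'   preserved and the crop offset recorded.
#' @export
crop_roi <- function(stack, roi) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames[[1]])
  roi <- as.integer(roi)
  if (length(roi) != 4L || roi[1] < 1L || roi[3] < 1L ||
      roi[2] > d[1] || roi[4] > d[2] || roi[1] > roi[2] || roi[3] > roi[4]) {
    stop_oomech("roi must be c(row_min, row_max, col_min, col_max) within the frame",
                "oomech_invalid_input")
  }
  frames <- lapply(stack$frames, function(f) f[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE])
  geom <- stack$geometry
  geom$crop_offset <- c(row = roi[1] - 1L, col = roi[3] - 1L)
  frame_stack(frames, frame_rate = stack$frame_rate,
              um_per_px = stack$um_per_px, truth = stack$truth,
              onset = stack$onset, geometry = geom)
}

#' Rotate every frame by a multiple of 90 degrees
#'
#' Orientation pre-step for recordings whose pipette is not horizontal with
#' the mouth opening leftwards.
#'
#' @param stack A [frame_stack()].
#' @param k Number of clockwise quarter turns.
#' @export
rotate_stack <- function(stack, k = 1L) {
  stopifnot(inherits(stack, "frame_stack"))
  k <- ((k %% 4) + 4) %% 4
  rot1 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  frames <- stack$frames
  if (k > 0) for (i in seq_len(k)) frames <- lapply(frames, rot1)
  frame_stack(frames, frame_rate = stack$frame_rate,
              um_per_px = stack$um_per_px, truth = stack$truth,
              onset = stack$onset, geometry = stack$geometry)
}

#' Track the aspirated zona tongue across frames
#'
#' For each frame, averages the intensity profile over the central lumen
#' rows right of the tip plane, normalises it between the tongue and lumen
#' background levels, and integrates the normalised step to a sub-pixel tip
#' position (pixels from the tip plane, positive into the lumen).
#'
#' @param stack A [frame_stack()].
#' @param start First frame to track (earlier frames still return positions;
#'   `start` merely marks the clip start carried through).
#' @return Numeric vector of per-frame tip positions in pixels.
#' @export
track_aspirated_zona <- function(stack, start = 1L) {
  stopifnot(inherits(stack, "frame_stack"))
  if (start < 1L || start > length(stack$frames)) {
    stop_oomech("start frame out of range", "oomech_invalid_input")
  }
  geo <- detect_pipette(stack$frames[[1]])
  band <- round(geo$cy + c(-1, 1) * 0.6 * geo$half_width)
  band <- max(1, band[1]):min(nrow(stack$frames[[1]]), band[2])
  nx <- ncol(stack$frames[[1]])
  cols <- (geo$x_tip + 1L):nx
  vapply(stack$frames, function(f) {
    f <- normalize_frame(f)
    prof <- colMeans(f[band, cols, drop = FALSE])
    fg <- stats::median(prof[1:max(2L, min(4L, length(prof)))])
    bg <- stats::median(prof[(length(prof) - 9L):length(prof)])
    if (fg - bg < 0.2) {
      stop_oomech("tongue/background contrast lost while tracking",
                  "oomech_detection_error")
    }
    p <- (prof - bg) / (fg - bg)
    # drop the last few columns so edge artefacts never enter the integral
    sum(pmin(pmax(p[1:(length(p) - 3L)], 0), 1))
  }, numeric(1))
}

#' Select the clip start frame
#'
#' Returns the index of the frame immediately before the first frame whose
#' tongue displacement from the pre-suction baseline exceeds
#' `motion_threshold` pixels.
#'
#' @param stack A [frame_stack()], or a numeric vector of already-tracked
#'   tip positions in pixels.
#' @param motion_threshold Displacement threshold in pixels.
#' @return Integer frame index.
#' @export
select_start_frame <- function(stack, motion_threshold = 1) {
  positions <- if (inherits(stack, "frame_stack"))
    track_aspirated_zona(stack) else as.numeric(stack)
  moved <- which(abs(positions - positions[1]) > motion_threshold)
  if (length(moved) == 0L) {
    stop_oomech("no motion detected in the stack", "oomech_no_motion")
  }
  max(1L, moved[1] - 1L)
}

#' Zona pellucida thickness at the pipette mouth
#'
#' Measures the bright zona annulus along the pipette axis in the first
#' frame: the radial run of zona intensity immediately outside the tip
#' plane.
#'
#' @param first_frame Grayscale matrix.
#' @param scale Micrometers per pixel.
#' @return Thickness in micrometers.
#' @export
measure_zona_thickness <- function(first_frame, scale) {
  check_positive(scale, "scale")
  geo <- detect_pipette(first_frame)
  f <- normalize_frame(first_frame)
  band <- round(geo$cy + (-2:2))
  band <- band[band >= 1 & band <= nrow(f)]
  prof <- colMeans(f[band, , drop = FALSE])
  x <- geo$x_tip - 1L
  if (x < 2L || prof[x] < 0.5) {
    stop_oomech("zona annulus not found at the pipette mouth",
                "oomech_detection_error")
  }
  run <- 0L
  while (x >= 1L && prof[x] > 0.5) {
    run <- run + 1L
    x <- x - 1L
  }
  run * scale
}

#' Pipette inner diameter in pixels
#'
#' Width of the dark lumen between the two wall bands, measured on the
#' first frame; invariant to affine intensity rescaling.
#'
#' @param first_frame Grayscale matrix.
#' @return Inner diameter in pixels.
#' @export
measure_pipette_inner_diameter <- function(first_frame) {
  geo <- detect_pipette(first_frame)
  geo$lumen_bot - geo$lumen_top + 1
}

#' Clip tracked positions to the motion window
#'
#' Drops the pre-suction static frames (keeping their median as the resting
#' baseline) and any frames beyond the analysis window, then emits times as
#' frame offsets over the frame rate starting at 0 at the first moved
#' frame. If even the second frame has moved past the threshold, the whole
#' record is treated as already clipped and returned unchanged.
#'
#' @param positions Per-frame tongue positions in pixels.
#' @param frame_rate Frames per second.
#' @param motion_threshold Displacement defining "moved", pixels.
#' @param window Maximum clip length in seconds.
#' @return List with `times` (s), `positions` (px) and `baseline` (px).
#' @export
compress_time_vector <- function(positions, frame_rate, motion_threshold = 1,
                                 window = 0.5) {
  check_positive(frame_rate, "frame_rate")
  if (length(positions) == 0L) {
    stop_oomech("no positions to compress", "oomech_no_motion")
  }
  disp <- abs(positions - positions[1])
  moved <- which(disp > motion_threshold)
  if (length(moved) == 0L) {
    stop_oomech("no motion detected in the position record", "oomech_no_motion")
  }
  first_moved <- moved[1]
  start <- if (first_moved <= 2L) 1L else first_moved
  baseline <- if (start == 1L) positions[1] else
    stats::median(positions[1:(start - 1L)])
  n_max <- floor(window * frame_rate) + 1L
  idx <- start:min(length(positions), start + n_max - 1L)
  list(times = (seq_along(idx) - 1L) / frame_rate,
       positions = positions[idx], baseline = baseline)
}

#' Convert pixel positions to micrometer depths
#'
#' `conversion_factor` is micrometers per pixel, calibrated from an object
#' of known size in frame; by default the pipette inner diameter (known in
#' micrometers, measured in pixels) is that object, which also normalises
#' away differences in video resolution.
#'
#' @param positions Positions in pixels.
#' @param conversion_factor Micrometers per pixel.
#' @return Depths in micrometers.
#' @export
to_micrometers <- function(positions, conversion_factor) {
  check_positive(conversion_factor, "conversion_factor")
  positions * conversion_factor
}

#' Tip positions from a manual-label table
#'
#' Fallback path mirroring hand-labelled recordings: a CSV with columns
#' `frame` and `position_px` replaces automatic tongue tracking.
#'
#' @param path CSV file path.
#' @return Numeric vector of positions ordered by frame.
#' @export
positions_from_labels <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("frame", "position_px") %in% names(df)))
  df$position_px[order(df$frame)]
}

#' Full video-analysis chain for one stack
#'
#' Detects the pipette, calibrates the conversion factor from its known
#' inner diameter, tracks the tongue, selects the clip start, compresses to
#' the motion window and converts to micrometers. The emitted depths are
#' relative to the resting zona position (the creep displacement the Zener
#' model describes); the resting position itself, in micrometers, is the
#' initial aspiration depth and is reported as the zona thickness estimate.
#'
#' @param stack A [frame_stack()].
#' @param pipette_inner_diameter_um Known lumen diameter for calibration.
#' @param motion_threshold Motion threshold in pixels.
#' @param window Clip window in seconds.
#' @return An [aspiration_curve()].
#' @export
track_stack <- function(stack, pipette_inner_diameter_um = 50,
                        motion_threshold = 1, window = 0.5) {
  stopifnot(inherits(stack, "frame_stack"))
  diam_px <- measure_pipette_inner_diameter(stack$frames[[1]])
  cf <- pipette_inner_diameter_um / diam_px
  positions <- track_aspirated_zona(stack)
  clip <- compress_time_vector(positions, stack$frame_rate,
                               motion_threshold = motion_threshold,
                               window = window)
  depths <- to_micrometers(pmax(clip$positions - clip$baseline, 0), cf)
  zt <- tryCatch(
    measure_zona_thickness(stack$frames[[1]], cf),
    oomech_detection_error = function(e) to_micrometers(clip$baseline, cf))
  aspiration_curve(clip$times, depths, frame_rate = stack$frame_rate,
                   zona_thickness = zt,
                   pipette_inner_diameter = pipette_inner_diameter_um,
                   conversion_factor = cf)
}
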