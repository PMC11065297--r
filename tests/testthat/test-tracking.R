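# Video analysis: rendering contract, boundary measurements, tongue
# tracking, clipping, calibration.

render_fixture <- function(seed = 5, noise_sd = 0.2) {
  cached(sprintf("stack_%d_%g", seed, noise_sd), {
    cv <- generate_curve(ref_params(), F0_DEFAULT, noise_sd = noise_sd,
                         seed = seed)
    list(curve = cv, stack = render_frame_stack(cv, seed = seed + 100))
  })
}

test_that("rendered tip positions encode zona thickness plus depth", {
  fx <- render_fixture()
  st <- fx$stack
  zt <- st$geometry$zona_thickness_um
  expect_equal(st$truth$tip_px,
               (zt + c(rep(0, st$geometry$n_lead), fx$curve$depths)) /
                 st$um_per_px)
  expect_equal(round(st$truth$tip_px[st$onset]),
               round((zt + fx$curve$depths[1]) / st$um_per_px))
})

test_that("a zero-depth curve renders a static stack", {
  cv0 <- aspiration_curve((0:20) / 70, rep(0, 21), frame_rate = 70)
  st <- render_frame_stack(cv0, noise_sd = 0, n_lead = 2L)
  expect_true(all(vapply(st$frames, identical, logical(1), st$frames[[1]])))
  expect_error(select_start_frame(st), class = "oomech_no_motion")
})

test_that("depths outside the rendered lumen are a geometry error", {
  cv <- aspiration_curve(c(0, 1 / 70), c(0, 500), frame_rate = 70)
  expect_error(render_frame_stack(cv), class = "oomech_geometry_error")
})

test_that("boundary measurements match the rendered geometry", {
  st <- render_fixture()$stack
  f1 <- st$frames[[1]]
  d_px <- measure_pipette_inner_diameter(f1)
  expect_lt(abs(d_px - 50 / st$um_per_px), 1.5)
  # invariant to affine intensity rescaling
  expect_equal(measure_pipette_inner_diameter(f1 * 0.4 + 0.3), d_px)
  zt <- measure_zona_thickness(f1, st$um_per_px)
  expect_lt(abs(zt - st$geometry$zona_thickness_um), 1 * st$um_per_px)
  # linear in the pixel scale
  expect_equal(measure_zona_thickness(f1, 2 * st$um_per_px), 2 * zt)
  blank <- matrix(0.5, 160, 280)
  expect_error(measure_pipette_inner_diameter(blank),
               class = "oomech_detection_error")
  expect_error(measure_zona_thickness(blank, 0.5),
               class = "oomech_detection_error")
})

test_that("tongue tracking follows the ground truth within a pixel", {
  fx <- render_fixture()
  pos <- track_aspirated_zona(fx$stack)
  expect_true(all(abs(pos - fx$stack$truth$tip_px) <= 1))
})

test_that("start-frame selection returns the frame before first motion", {
  # synthetic position record: static through frame 9, moving from frame 10
  pos <- c(rep(30, 9), 30 + cumsum(rep(2, 8)))
  expect_identical(select_start_frame(pos, motion_threshold = 1), 9L)
  fx <- render_fixture()
  expect_identical(select_start_frame(fx$stack), fx$stack$onset - 1L)
})

test_that("time compression clips to the motion window", {
  pos <- c(rep(10, 6), 10 + cumsum(rep(3, 50)))
  cl <- compress_time_vector(pos, 70)
  expect_equal(cl$times[1], 0)
  expect_length(cl$times, 36L)
  expect_equal(max(cl$times), 0.5)
  expect_equal(cl$baseline, 10)
  expect_equal(cl$positions[1], 13)  # first moved frame retained
  # an already-clipped motion record passes through unchanged
  moving <- 10 + cumsum(rep(3, 36))
  cl2 <- compress_time_vector(moving, 70)
  expect_equal(cl2$positions, moving)
  expect_error(compress_time_vector(rep(5, 20), 70), class = "oomech_no_motion")
})

test_that("pixel-to-micrometer conversion is exact arithmetic", {
  expect_equal(to_micrometers(30, 50 / 100), 15)
  expect_equal(to_micrometers(c(1, 2, 4), 1), c(1, 2, 4))
  expect_error(to_micrometers(5, 0), class = "oomech_invalid_input")
})

test_that("cropping preserves geometry and tracking results", {
  fx <- render_fixture()
  st <- fx$stack
  d <- dim(st$frames[[1]])
  full <- crop_roi(st, c(1, d[1], 1, d[2]))
  expect_identical(full$frames, st$frames)
  expect_error(crop_roi(st, c(1, d[1], 1, d[2] + 5)),
               class = "oomech_invalid_input")
  # trimming margin rows/cols leaves tip-relative depths unchanged
  cr <- crop_roi(st, c(11, d[1] - 10, 21, d[2]))
  c_full <- track_stack(st)
  c_crop <- track_stack(cr)
  n <- min(length(c_full$depths), length(c_crop$depths))
  expect_lt(max(abs(c_full$depths[1:n] - c_crop$depths[1:n])), 0.5)
})

test_that("rotation pre-step restores a horizontal pipette", {
  fx <- render_fixture()
  st4 <- rotate_stack(fx$stack, 4)
  expect_equal(st4$frames[[1]], fx$stack$frames[[1]])
  st1 <- rotate_stack(fx$stack, 1)
  expect_equal(dim(st1$frames[[1]]), rev(dim(fx$stack$frames[[1]])))
  back <- rotate_stack(st1, 3)
  expect_equal(back$frames[[10]], fx$stack$frames[[10]])
})

test_that("the full chain recovers the generating curve (closed loop)", {
  fx <- render_fixture()
  tc <- track_stack(fx$stack)
  n <- min(length(tc$depths), length(fx$curve$depths))
  expect_gte(n, 30L)
  expect_true(all(tc$times >= 0 & tc$times <= 0.5))
  expect_lt(max(abs(tc$depths[1:n] - fx$curve$depths[1:n])),
            1 * fx$stack$um_per_px)
  # conversion calibrated from the pipette: scale-invariance of depths
  expect_equal(tc$conversion_factor * measure_pipette_inner_diameter(
    fx$stack$frames[[1]]), 50, tolerance = 1e-9)
})

test_that("frame stacks round-trip through PNG + JSON", {
  fx <- render_fixture()
  dir <- tempfile("stack")
  write_frame_stack(fx$stack, dir)
  back <- read_frame_stack(dir)
  expect_equal(length(back$frames), length(fx$stack$frames))
  expect_equal(back$frame_rate, fx$stack$frame_rate)
  expect_equal(back$um_per_px, fx$stack$um_per_px)
  # PNG quantises to 1/255; tracking still works on the reloaded stack
  tc <- track_stack(back)
  tc0 <- track_stack(fx$stack)
  n <- min(length(tc$depths), length(tc0$depths))
  expect_lt(max(abs(tc$depths[1:n] - tc0$depths[1:n])), 0.5)
  unlink(dir, recursive = TRUE)
})

test_that("manual position labels substitute for automatic tracking", {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(frame = c(2, 1, 3), position_px = c(20, 10, 30)),
                   f, row.names = FALSE)
  expect_equal(positions_from_labels(f), c(10, 20, 30))
})
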