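# Frame I/O, skin-region detection, track stabilization and cropping.

test_that("write_frames / load_frames round-trips 8-bit-representable frames", {
  set.seed(1)
  arr <- array(sample(0:255, 16 * 16 * 3 * 3, replace = TRUE) / 255,
               dim = c(16, 16, 3, 3))
  st <- frame_stack(arr, fps = 30)
  dir <- withr::local_tempdir()
  write_frames(st, dir)
  expect_length(list.files(dir, pattern = "\\.png$"), 3)
  back <- load_frames(dir, fps = 30)
  expect_equal(back$frames, st$frames, tolerance = 1e-12)
  expect_equal(back$fps, 30)
})

test_that("load_frames rejects empty and mixed-size sequences", {
  dir <- withr::local_tempdir()
  expect_error(load_frames(dir, 30), "no frames")
  png::writePNG(array(0.5, c(64, 64, 3)), file.path(dir, "a.png"))
  png::writePNG(array(0.5, c(32, 32, 3)), file.path(dir, "b.png"))
  expect_error(load_frames(dir, 30), "mixed frame sizes")
})

test_that("skin detector finds a constant box covering a synthetic skin patch", {
  st <- solid_stack(c(0.5, 0.5, 0.5), h = 32, w = 32, nt = 5)
  st <- paint_patch(st, roi_box(8, 10, 12, 9), c(0.8, 0.55, 0.45))
  track <- detect_face_track(st)
  expect_true(all(track$detector_hits))
  expect_true(all(track$boxes[, "x"] == 8 & track$boxes[, "y"] == 10 &
                  track$boxes[, "w"] == 12 & track$boxes[, "h"] == 9))
})

test_that("with two skin regions the larger one is kept", {
  st <- solid_stack(c(0.5, 0.5, 0.5), h = 40, w = 40, nt = 2)
  st <- paint_patch(st, roi_box(2, 2, 6, 6), c(0.8, 0.55, 0.45))
  st <- paint_patch(st, roi_box(20, 20, 14, 12), c(0.8, 0.55, 0.45))
  track <- detect_face_track(st)
  expect_true(all(track$boxes[, "x"] == 20 & track$boxes[, "w"] == 14))
})

test_that("all-gray frames yield no detection and an error", {
  st <- solid_stack(c(0.5, 0.5, 0.5), nt = 3)
  expect_error(detect_face_track(st), "no face region")
})

test_that("missed detections carry the last (or first) successful box", {
  st <- solid_stack(c(0.5, 0.5, 0.5), h = 32, w = 32, nt = 4)
  skin <- c(0.8, 0.55, 0.45)
  # skin patch visible only in frames 2 and 3, at different positions
  for (ch in 1:3) {
    st$frames[5:14, 5:14, ch, 2] <- skin[ch]
    st$frames[15:24, 15:24, ch, 3] <- skin[ch]
  }
  track <- detect_face_track(st)
  expect_identical(track$detector_hits, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(track$boxes[1, ], track$boxes[2, ])  # leading miss -> first hit
  expect_equal(track$boxes[4, ], track$boxes[3, ])  # trailing miss -> carry forward
})

test_that("stabilization commits only above-threshold jumps", {
  # jitter < threshold: all boxes equal the first
  jitter <- cbind(x = c(10, 11, 10, 12, 11), y = c(10, 10, 11, 10, 9),
                  w = 8, h = 8)
  out <- stabilize_track(roi_track(jitter), translation_threshold_px = 5)
  expect_true(all(out$boxes[, "x"] == 10 & out$boxes[, "y"] == 10))

  # one jump of 2x threshold at frame 3: output changes there and only there
  jump <- cbind(x = c(10, 10, 30, 30, 30), y = 10, w = 8, h = 8)
  out <- stabilize_track(roi_track(jump), translation_threshold_px = 10)
  expect_equal(out$boxes[, "x"], c(10, 10, 30, 30, 30))

  # threshold 0: centres track the raw centres exactly (size still frozen)
  raw <- cbind(x = c(10, 12, 14, 13), y = c(5, 6, 7, 8), w = 8, h = 8)
  out <- stabilize_track(roi_track(raw), translation_threshold_px = 0)
  expect_equal(out$boxes[, "x"], raw[, "x"])
  expect_equal(out$boxes[, "y"], raw[, "y"])
})

test_that("stabilization freezes the box size and never adds distinct boxes", {
  set.seed(3)
  raw <- cbind(x = cumsum(sample(-3:3, 40, TRUE)) + 20,
               y = cumsum(sample(-3:3, 40, TRUE)) + 20,
               w = sample(8:10, 40, TRUE), h = sample(8:10, 40, TRUE))
  out <- stabilize_track(roi_track(raw), translation_threshold_px = 4)
  expect_true(all(out$boxes[, "w"] == raw[1, "w"]))
  expect_true(all(out$boxes[, "h"] == raw[1, "h"]))
  expect_lte(nrow(unique(out$boxes)), nrow(unique(raw)))
})

test_that("cropping returns the boxed region, with edge padding when clamped", {
  set.seed(4)
  arr <- array(runif(20 * 20 * 3 * 2), dim = c(20, 20, 3, 2))
  st <- frame_stack(arr, fps = 30)

  # full-frame box is the identity
  full <- crop_to_roi(st, fixed_track(st, roi_box(0, 0, 20, 20)))
  expect_equal(full$frames, st$frames)

  # 10x10 at the origin is the top-left corner
  tl <- crop_to_roi(st, fixed_track(st, roi_box(0, 0, 10, 10)))
  expect_equal(tl$frames, st$frames[1:10, 1:10, , , drop = FALSE])

  # box 2 px past the right edge: clamped then edge-replicated
  over <- crop_to_roi(st, fixed_track(st, roi_box(12, 0, 10, 10)))
  manual <- st$frames[1:10, c(13:20, 20, 20), , , drop = FALSE]
  expect_equal(over$frames, manual)

  # fully outside is an error
  expect_error(crop_to_roi(st, fixed_track(st, roi_box(25, 0, 5, 5))), "outside")
})

test_that("cropping commutes with channel averaging", {
  st <- tiny_study(duration_s = 5, seed = 9)
  box <- st$roi_truth
  cropped_mean <- channel_mean_signal(crop_to_roi(st$video, fixed_track(st$video, box)), "R")
  # oracle: restrict the per-frame red plane to the box and average
  direct <- apply(st$video$frames[roi_rows(box), roi_cols(box), 1, , drop = FALSE],
                  4, mean)
  expect_equal(cropped_mean$values, direct, tolerance = 1e-12)
})
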