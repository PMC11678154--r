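test_that("read_stack orders TIFF pages in time and validates input", {
  frames <- array(stats::runif(6 * 5 * 4), c(6, 5, 4))
  s <- image_stack(frames, frame_interval = 5, pixel_size = 2)
  path <- tempfile(fileext = ".tif")
  write_stack(s, path)
  back <- read_stack(path)
  expect_equal(dim(back$frames), c(6, 5, 4))
  expect_equal(back$frames, frames, tolerance = 1e-6)
  expect_equal(back$origin_time + (4 - 1) * back$frame_interval,
               0 + 3 * 5)

  # single page is a valid one-frame stack
  p1 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 3, 3), p1, bits.per.sample = 32L)
  one <- read_stack(p1, frame_interval = 5, pixel_size = 1)
  expect_equal(dim(one$frames)[3], 1L)

  # ragged page shapes are rejected
  pr <- tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.1, 3, 3), matrix(0.1, 4, 3)), pr,
                  bits.per.sample = 32L)
  expect_error(read_stack(pr, frame_interval = 5, pixel_size = 1), "ragged")
  expect_error(read_stack(tempfile(), frame_interval = 5, pixel_size = 1),
               "no such file")
  expect_error(image_stack(frames, frame_interval = 0, pixel_size = 1),
               "frame_interval")
})

test_that("rebin sums blocks, preserves mass, and rescales the pixel pitch", {
  frames <- array(stats::runif(8 * 9 * 2), c(8, 9, 2))
  s <- image_stack(frames, 5, 1.1)
  rb <- rebin(s, 4)
  expect_equal(dim(rb$frames), c(2, 2, 2))
  expect_equal(rb$pixel_size, 4.4)
  # total intensity preserved over the retained region (cols 9 -> drop last)
  expect_equal(sum(rb$frames[, , 1]), sum(frames[1:8, 1:8, 1]))
  expect_equal(rb$frames[1, 1, 2], sum(frames[1:4, 1:4, 2]))
  # constant image: each binned pixel is factor^2 times the constant
  cs <- image_stack(array(3, c(8, 8, 1)), 5, 1)
  expect_true(all(rebin(cs, 4)$frames == 48))
  expect_identical(rebin(s, 1), s)
  expect_error(rebin(s, 0), "factor")
})

test_that("roi ladders form disjoint annular bands at the nominal distances", {
  s <- image_stack(array(1, c(81, 81, 2)), 5, 1.375)
  rois <- build_roi_ladder(s, c(40, 40), 10, 40, 5)
  expect_length(rois, 7L)
  expect_equal(vapply(rois, `[[`, numeric(1), "nominal_distance"),
               seq(10, 40, 5))
  # pairwise disjoint when band_width <= step
  total <- Reduce(`+`, lapply(rois, function(r) r$mask * 1L))
  expect_lte(max(total), 1L)
  # every band pixel sits within band_width/2 of its nominal distance
  for (r in rois) {
    idx <- which(r$mask, arr.ind = TRUE)
    d <- sqrt((idx[, 2] - 1 - 40)^2 + (idx[, 1] - 1 - 40)^2) * 1.375
    expect_true(all(abs(d - r$nominal_distance) <= 2.5 + 1e-9))
  }
  expect_error(build_roi_ladder(s, c(200, 40), 10, 40, 5), "outside")
  expect_error(build_roi_ladder(s, c(40, 40), 30, 10, 5), "start")
  # a band beyond the frame has no pixels
  expect_error(build_roi_ladder(s, c(40, 40), 300, 320, 10), "no pixels")
})

test_that("extract_traces averages ROI pixels and applies background", {
  frames <- array(0, c(10, 10, 3))
  frames[, , 1] <- 4; frames[, , 2] <- 6; frames[, , 3] <- 10
  s <- image_stack(frames, 2, 1, origin_time = 1)
  roi <- roi_rect(0, 4, 0, 4, 10, 10, nominal_distance = 5)
  tr <- extract_traces(s, roi)[[1]]
  expect_equal(tr$values, c(4, 6, 10))
  expect_equal(tr$times, c(1, 3, 5))
  # background identical to signal: all-zero trace
  tr0 <- suppressWarnings(extract_traces(s, roi, background = roi))[[1]]
  expect_equal(tr0$values, c(0, 0, 0))
  expect_warning(extract_traces(s, roi, background = roi), "overlaps")
  bad <- roi_rect(0, 1, 0, 1, 5, 5, nominal_distance = 1)
  expect_error(extract_traces(s, bad), "frame size")
  expect_error(roi_spec(matrix(FALSE, 3, 3), 1), "no pixels")
})

test_that("trace extraction is linear in the stack", {
  f1 <- array(stats::runif(49 * 2), c(7, 7, 2))
  f2 <- array(stats::runif(49 * 2), c(7, 7, 2))
  roi <- roi_rect(1, 5, 2, 6, 7, 7, nominal_distance = 3)
  tr <- function(f) extract_traces(image_stack(f, 5, 1), roi)[[1]]$values
  expect_equal(tr(2 * f1 + 3 * f2), 2 * tr(f1) + 3 * tr(f2),
               tolerance = 1e-12)
})

test_that("rebin commutes with extraction for block-aligned ROIs", {
  frames <- array(stats::runif(8 * 8 * 3), c(8, 8, 3))
  s <- image_stack(frames, 5, 1)
  # 4x4-aligned ROI: pixels 0..3 in both axes -> binned pixel (0,0)
  roi_full <- roi_rect(0, 3, 0, 3, 8, 8, nominal_distance = 2)
  roi_binned <- roi_rect(0, 0, 0, 0, 2, 2, nominal_distance = 2)
  a <- extract_traces(rebin(s, 4), roi_binned)[[1]]$values
  b <- extract_traces(s, roi_full)[[1]]$values * 16  # sum-binned block
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("trace CSV serialization round-trips", {
  tr <- simulate_traces(small_preset("control_embryo", n_frames = 10L),
                        noise_free = TRUE)
  path <- tempfile(fileext = ".csv")
  write_traces_csv(tr, path)
  back <- read_traces_csv(path)
  back <- back[order(vapply(back, `[[`, numeric(1), "distance"))]
  for (i in seq_along(tr)) {
    expect_equal(back[[i]]$values, tr[[i]]$values, tolerance = 1e-12)
    expect_equal(back[[i]]$distance, tr[[i]]$distance)
  }
})
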