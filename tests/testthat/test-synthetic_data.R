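test_that("presets carry the documented experimental conditions", {
  expect_equal(make_preset("agarose_1pct")$D, 18.1)
  expect_equal(make_preset("agarose_2pct")$D, 8.9)
  expect_equal(make_preset("agarose_5pct")$D, 2.6)
  ctrl <- make_preset("control_embryo")
  expect_equal(ctrl$D, 12)
  expect_equal(ctrl$t0, 320)
  expect_equal(ctrl$roi_distances, seq(10, 40, 5))
  xg <- make_preset("xenograft_embryo")
  expect_equal(xg$D, 1.0)
  expect_equal(xg$t0, 600)
  expect_equal(make_preset("xenograft_variant_a")$D, 1.9)
  expect_equal(make_preset("xenograft_variant_b")$D, 0.82)
  ag <- make_preset("agarose_1pct")
  expect_equal(ag$t0, 0)
  expect_equal(ag$roi_distances, seq(30, 200, 10))
  expect_equal(ag$frame_interval, 5)
  expect_equal(ag$n_frames, 720L)
  expect_error(make_preset("agarose_10pct"), "unknown preset")
})

test_that("noise-free traces equal the model and decay with ROI distance", {
  p <- small_preset("control_embryo")
  tr <- simulate_traces(p, noise_free = TRUE)
  expect_length(tr, 7L)
  params <- diffusion_params(p$D, p$t0, p$B)
  for (t1 in tr)
    expect_equal(t1$values, dye_concentration(params, t1$distance, t1$times),
                 tolerance = 1e-14)
  first_vals <- vapply(tr, function(t1) t1$values[1], numeric(1))
  expect_true(all(diff(first_vals) < 0))
  # embryo presets decay monotonically in the recorded window (t0 > x^2/2D)
  expect_true(all(vapply(tr, function(t1) all(diff(t1$values) < 0), TRUE)))
})

test_that("far agarose ROIs rise then decay; near ones are past their peak", {
  p <- small_preset("agarose_1pct", n_frames = 400L)
  tr <- simulate_traces(p, noise_free = TRUE)
  far <- tr[[length(tr)]]             # 200 um: peak at 200^2/36.2 = 1105 s
  expect_gt(which.max(far$values), 5)
  expect_lt(which.max(far$values), length(far$values))
  near <- tr[[1]]                     # 30 um: peak at 24.9 s = frame 5
  expect_lt(which.max(near$values), 10)
  # t0 = 0 presets start the clock one frame after injection
  expect_equal(near$times[1], p$frame_interval)
})

test_that("noisy simulation is seed-reproducible and matches the noise law", {
  p <- small_preset("control_embryo", seed = 7L)
  a <- simulate_traces(p)
  b <- simulate_traces(p)
  expect_identical(traces_to_df(a), traces_to_df(b))
  p2 <- small_preset("control_embryo", seed = 8L)
  expect_false(identical(traces_to_df(a), traces_to_df(simulate_traces(p2))))

  # pooled variance across 200 seeded replicates ~ read^2 + shot * signal
  p$n_frames <- 12L
  p$roi_distances <- c(10, 25)
  clean <- simulate_traces(p, noise_free = TRUE)
  reps <- vapply(1:200, function(s) {
    p$noise <- noise_spec(seed = s)
    unlist(lapply(simulate_traces(p), `[[`, "values"))
  }, numeric(24L))
  expected <- p$noise$read_sigma^2 +
    p$noise$shot_scale * unlist(lapply(clean, `[[`, "values"))
  ratio <- mean(apply(reps, 1, stats::var) / expected)
  expect_lt(abs(ratio - 1), 0.10)
})

test_that("the pressure ramp adds an early linear rise near the source", {
  p <- small_preset("agarose_1pct", n_frames = 30L)
  p$roi_distances <- c(5, 30)
  p$pressure <- pressure_spec(ramp_rate = 50, ramp_duration = 10,
                              ramp_radius = 10)
  with_ramp <- simulate_traces(p, noise_free = TRUE)
  p$pressure <- NULL
  without <- simulate_traces(p, noise_free = TRUE)
  near_delta <- with_ramp[[1]]$values - without[[1]]$values
  # saturated contribution = rate * duration after the ramp window
  expect_equal(unique(round(near_delta[3:30], 9)), 50 * 10)
  expect_gt(near_delta[2], 0)
  # outside ramp_radius the ramp does not contribute
  expect_equal(with_ramp[[2]]$values, without[[2]]$values)
})

test_that("rendered stacks reproduce the trace generator over ROI bands", {
  p <- small_preset("control_embryo", n_frames = 25L)
  geom <- stack_geometry(81, 81, pixel_size = 1.375, source = c(40, 40))
  out <- render_stack(p, geom, noise_free = TRUE)
  rois <- build_roi_ladder(out$dye, c(40, 40), 10, 40, 5, band_width = 2)
  extracted <- extract_traces(out$dye, rois)
  reference <- simulate_traces(p, noise_free = TRUE)
  for (i in seq_along(extracted)) {
    rel <- abs(extracted[[i]]$values - reference[[i]]$values) /
      reference[[i]]$values
    expect_lt(max(rel), 0.02)
  }
  expect_equal(extracted[[1]]$times, reference[[1]]$times)
  # vessel channel is the static mask at constant intensity
  expect_setequal(unique(as.vector(out$vessel)), c(0, 100))
})

test_that("rendering rejects invalid geometry and seeds reproduce stacks", {
  p <- small_preset("control_embryo", n_frames = 4L)
  expect_error(stack_geometry(50, 50, source = c(60, 10)), "outside")
  g <- stack_geometry(31, 31, source = c(15, 15))
  a <- render_stack(p, g)
  b <- render_stack(p, g)
  expect_identical(a$dye$frames, b$dye$frames)
})

test_that("stack writing round-trips pixel data and sidecar metadata", {
  p <- small_preset("agarose_1pct", n_frames = 6L)
  g <- stack_geometry(41, 41, source = c(20, 20))
  out <- render_stack(p, g, noise_free = TRUE)
  path <- tempfile(fileext = ".tif")
  sidecar <- write_stack(out, path, truth = list(D_um2_s = p$D))
  expect_true(file.exists(sidecar))
  back <- read_stack(path)
  expect_equal(back$frames, out$dye$frames, tolerance = 1e-6)
  expect_equal(back$frame_interval, 5)
  expect_equal(back$origin_time, 5)  # t0 = 0 preset starts at one interval
  meta <- jsonlite::read_json(sidecar)
  expect_equal(meta$truth$D_um2_s, 18.1)
})
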