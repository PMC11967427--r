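# Synthetic scene generator: shape synthesis, rendering, ground truth.

test_that("a circularity-1, aspect-1 grain is a disk of the requested size", {
  m <- make_grain_mask(360, 1, 1, pixel_scale = 18, seed = 1)
  st <- attr(m, "stats")
  expect_lt(abs(st$feret_max_px - 20) / 20, 0.15)
  expect_gt(st$circularity, 0.85)
  expect_lt(st$aspect_ratio, 1.5)
})

test_that("grain masks hit measured shape targets within tolerance", {
  # polypropylene-like: 292.8 um, circularity 0.62, aspect 2.26
  for (s in 1:5) {
    m <- make_grain_mask(292.8, 0.62, 2.26, seed = s)
    st <- attr(m, "stats")
    expect_lt(abs(st$feret_max_px * 18 - 292.8) / 292.8, 0.15)
    expect_lt(abs(st$circularity - 0.62), 0.15)
    expect_lt(abs(st$aspect_ratio - 2.26), 0.5)
    # connected
    expect_equal(max(flowmp:::.label8_cpp(m)), 1L)
  }
  expect_error(make_grain_mask(20, 0.5, 2), "pixel")
  expect_error(make_grain_mask(200, 1.3, 1), "circularity")
})

test_that("unreachable grain targets error with closest achieved values", {
  # a perfect circle cannot have aspect ratio 3
  expect_error(make_grain_mask(360, 1.0, 3.0, seed = 2, max_tries = 20),
               "closest achieved")
})

test_that("fiber masks are thin, elongated, and shorten with curvature", {
  straight <- make_fiber_mask(540, 2, 0, seed = 3)
  st <- attr(straight, "stats")
  expect_gt(st$aspect_ratio, 8)
  expect_lt(abs(st$feret_max_px - 30), 4)
  expect_equal(max(flowmp:::.label8_cpp(straight)), 1L)

  curved <- make_fiber_mask(540, 2, 1, seed = 3)
  expect_lt(attr(curved, "stats")$feret_max_px, st$feret_max_px)

  # any typical fiber is rough-classified as fiber
  for (s in 1:8) {
    f <- make_fiber_mask(runif(1, 400, 900), sample(1:2, 1),
                         runif(1, 0, 0.5), seed = s)
    expect_equal(as.character(rough_classify(attr(f, "stats"))), "fiber")
  }
  expect_error(make_fiber_mask(0, 2), "degenerate")
  expect_error(make_fiber_mask(90, 2), "width")
})

test_that("empty scene renders constant background with no candidates", {
  cfg <- scene_config(n_grains = 0, n_fibers = 0, n_distractors = 0,
                      background_noise_sd = 0, n_frames = 5, seed = 1)
  sim <- render_video(cfg)
  expect_equal(nrow(sim$truth$particles), 0L)
  for (t in 1:5) {
    cand <- extract_candidates(canny_edges(sim$frames$frames[[t]]),
                               sim$frames$frames[[t]], cfg$window)
    expect_equal(nrow(cand), 0L)
  }
})

test_that("pure advection moves centroids by exactly the flow velocity", {
  cfg <- scene_config(n_grains = 1, n_fibers = 0, n_distractors = 0,
                      background_noise_sd = 0, pulsation_duty = 1,
                      n_frames = 20, flow_velocity_px_per_frame = 8,
                      seed = 4)
  sim <- render_video(cfg)
  tr <- sim$truth$trajectory
  expect_equal(diff(tr$x), rep(8, 19))
  expect_equal(diff(tr$y), rep(0, 19))
})

test_that("pulsation pauses trajectories during the off fraction", {
  cfg <- scene_config(n_grains = 1, n_fibers = 0, n_distractors = 0,
                      background_noise_sd = 0, pulsation_duty = 0.5,
                      pulsation_period_frames = 10, n_frames = 20, seed = 4)
  sim <- render_video(cfg)
  dx <- diff(sim$truth$trajectory$x)
  expect_true(all(dx %in% c(0, 8)))
  # the step from frame t to t+1 follows frame t's pulse state
  expect_equal(sum(dx == 8), sum(flowmp:::pulse_moving(1:19, 10, 0.5)))
  # monotone in the flow direction
  expect_true(all(dx >= 0))
})

test_that("identical config and seed give bit-identical video and truth", {
  cfg <- scene_config(n_frames = 15, seed = 12)
  a <- render_video(cfg)
  b <- render_video(cfg)
  expect_identical(a$frames$frames, b$frames$frames)
  expect_identical(a$truth$particles, b$truth$particles)
  expect_identical(a$truth$trajectory, b$truth$trajectory)
})

test_that("window wider than the frame is rejected", {
  expect_error(scene_config(window = det_window(0, 0, 500, 100)),
               "window")
})

test_that("particle brightness floor stays above the distractor ceiling", {
  # distractors are rendered at <= 30% of the 180 brightness floor and
  # heavily defocused; no composited distractor pixel may approach the floor
  cfg <- scene_config(n_grains = 0, n_fibers = 0, n_distractors = 4,
                      background_noise_sd = 0, n_frames = 10, seed = 5)
  sim <- render_video(cfg)
  peak <- max(vapply(sim$frames$frames, max, numeric(1)))
  expect_lt(peak, 0.3 * 180 + 7)   # background level + ceiling
})

test_that("scene written to disk round-trips through read_frames", {
  cfg <- scene_config(n_frames = 4, n_grains = 2, n_fibers = 1, seed = 9)
  sim <- render_video(cfg)
  dir <- withr::local_tempdir()
  write_scene(sim, dir, cfg)
  expect_true(file.exists(file.path(dir, "scene_config.yaml")))
  back <- read_frames(dir, pixel_scale_um = cfg$pixel_scale_um)
  expect_equal(back$n_frames, 4L)
  expect_identical(back$frames[[2]], sim$frames$frames[[2]])
})
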