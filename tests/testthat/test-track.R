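# Cross-frame linking and exactly-once counting.

test_that("a candidate at the predicted position links; lateral outliers do not", {
  prev <- make_cand(1, 10, 20)
  curr <- make_cand(2, 18, 20)
  m <- link_frames(prev, curr, link_params(expected_flow_dx_px = 8))
  expect_equal(m, 1L)

  far <- make_cand(2, 10, 60)
  expect_true(is.na(link_frames(prev, far,
                                link_params(max_lateral_dy_px = 10))))

  # size-ratio gate
  big <- make_cand(2, 18, 20, feret = 30)
  expect_true(is.na(link_frames(prev, big,
                                link_params(max_ratio_change = 2))))
})

test_that("three advected particles give exactly three tracks (oracle check)", {
  # analytic trajectories: 3 particles, 8 px/frame, 5 frames
  ys <- c(30, 60, 90)
  cands <- lapply(1:5, function(t) {
    do.call(rbind, lapply(1:3, function(i) {
      make_cand(t, 10 + 8 * (t - 1) + i, ys[i], feret = 8 + i)
    }))
  })
  tracks <- track_particles(cands)
  expect_equal(length(tracks), 3L)
  # each track follows one y-lane (the brute-force optimal assignment)
  lanes <- sort(vapply(tracks, function(tr) tr$cand$cy[1], numeric(1)))
  expect_equal(lanes, ys)
  for (tr in tracks) {
    expect_equal(nrow(tr$cand), 5L)
    expect_true(all(diff(tr$cand$frame) == 1))
    expect_equal(length(unique(tr$cand$cy)), 1L)
  }
})

test_that("shuffling candidate order within frames does not change tracks", {
  set.seed(5)
  ys <- c(30, 55, 80, 105)
  cands <- lapply(1:6, function(t) {
    df <- do.call(rbind, lapply(1:4, function(i) {
      make_cand(t, 12 + 8 * (t - 1) + 2 * i, ys[i], feret = 6 + i)
    }))
    df[sample(nrow(df)), , drop = FALSE]
  })
  t1 <- track_particles(cands)
  cands2 <- lapply(cands, function(df) df[sample(nrow(df)), , drop = FALSE])
  t2 <- track_particles(cands2)
  sig <- function(tracks) {
    s <- lapply(tracks, function(tr) tr$cand[order(tr$cand$frame),
                                             c("frame", "cx", "cy")])
    s[order(vapply(s, function(d) d$cy[1], numeric(1)))]
  }
  expect_equal(sig(t1), sig(t2), ignore_attr = TRUE)
})

test_that("a particle visible for many frames is counted exactly once", {
  cands <- lapply(1:12, function(t) make_cand(t, 10 + 8 * (t - 1), 50))
  tracks <- track_particles(cands)
  counted <- count_events(tracks, det_window(0, 0, 200, 100))
  expect_equal(length(counted), 1L)
  expect_equal(nrow(counted[[1]]$cand), 12L)
})

test_that("gap bridging keeps one track across short detection dropouts", {
  # candidate missing on frames 4-5 (e.g. a pump pause with a dropout)
  frames_present <- c(1, 2, 3, 6, 7)
  cands <- lapply(1:7, function(t) {
    if (t %in% frames_present) make_cand(t, 10 + 8 * (t - 1), 50)
    else flowmp:::empty_candidates()
  })
  tracks <- track_particles(cands, link_params(max_gap_frames = 2,
                                               max_link_distance_px = 12))
  expect_equal(length(tracks), 1L)
  expect_equal(nrow(tracks[[1]]$cand), 5L)
  # with no gap bridging the dropout splits the track
  tracks2 <- track_particles(cands, link_params(max_gap_frames = 0))
  expect_equal(length(tracks2), 2L)
})

test_that("a paused particle (pump off) stays one track and one count", {
  cfg <- scene_config(n_grains = 1, n_fibers = 0, n_distractors = 0,
                      background_noise_sd = 0, pulsation_duty = 0.5,
                      pulsation_period_frames = 8, n_frames = 60, seed = 21)
  sim <- render_video(cfg)
  counted <- count_events(
    track_particles(detect_frames(sim$frames, cfg$window)), cfg$window)
  expect_equal(length(counted), 1L)
  expect_equal(truth_traversals(sim$truth), 1L)
})

test_that("representative candidate is the largest-area member", {
  cands <- lapply(1:5, function(t) {
    make_cand(t, 10 + 8 * (t - 1), 50, area = c(10, 40, 90, 40, 10)[t])
  })
  counted <- count_events(track_particles(cands), det_window(0, 0, 100, 100))
  expect_equal(counted[[1]]$representative$frame, 3L)
  expect_equal(counted[[1]]$representative$area_px, 90)
})

test_that("touching particles merge into one track (known undercount mode)", {
  # two particles placed so their masks overlap throughout the pass
  cfg <- scene_config(n_grains = 2, n_fibers = 0, n_distractors = 0,
                      background_noise_sd = 0, staining_unevenness = 0,
                      n_frames = 80, seed = 31,
                      start_positions = cbind(c(60, 62), c(120, 121)))
  sim <- render_video(cfg)
  expect_gt(nrow(sim$truth$touching), 0)
  counted <- count_events(
    track_particles(detect_frames(sim$frames, cfg$window)), cfg$window)
  expect_equal(length(counted), 1L)   # merged: undercount measured below
  eff <- detection_efficiency(
    data.frame(frame = vapply(counted, function(tr) tr$representative$frame,
                              numeric(1)),
               centroid_x = vapply(counted, function(tr) tr$representative$cx,
                                   numeric(1)),
               centroid_y = vapply(counted, function(tr) tr$representative$cy,
                                   numeric(1))),
    sim$truth)
  expect_lt(eff$efficiency_pct, 100)
  expect_equal(length(eff$merged_truth_ids), 1L)
})
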