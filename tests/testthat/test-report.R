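# Records, crops, CSV schema, summary totals, overlay.

test_that("an empty run writes an empty CSV with the fixed header", {
  dir <- withr::local_tempdir()
  stack <- frame_stack(list(matrix(0L, 40, 40)), 18)
  res <- emit_records(list(), stack, NULL, dir, run_id = "t")
  expect_equal(nrow(res$records), 0L)
  expect_equal(res$summary$total_count, 0L)
  csv <- read.csv(file.path(dir, "t_records.csv"))
  expect_equal(names(csv), flowmp:::RECORD_COLUMNS)
  expect_equal(nrow(csv), 0L)
})

test_that("records, crops and summary are consistent on a clean scene", {
  sc <- clean_scene()
  cfg <- sc$cfg; sim <- sc$sim
  counted <- count_events(
    track_particles(detect_frames(sim$frames, cfg$window)), cfg$window)
  dir <- withr::local_tempdir()
  res <- emit_records(counted, sim$frames, NULL, dir, run_id = "sc")
  records <- res$records

  # one record per counted track; totals partition
  expect_equal(nrow(records), length(counted))
  expect_equal(res$summary$total_count, nrow(records))
  expect_equal(sum(unlist(res$summary$count_by_class)), nrow(records))
  expect_equal(sum(unlist(res$summary$count_by_category)), nrow(records))

  # class counts match ground truth (rough classifier on clean shapes)
  truth_classes <- table(sim$truth$particles$true_class)
  expect_equal(unname(res$summary$count_by_class["fiber"]),
               unname(truth_classes[["fiber"]]))
  expect_equal(unname(res$summary$count_by_class["grain"]),
               unname(truth_classes[["grain"]]))

  # CSV <-> crop files are a bijection
  expect_equal(anyDuplicated(records$crop_file), 0L)
  for (f in records$crop_file) {
    expect_true(file.exists(file.path(dir, f)))
    expect_true(file.exists(file.path(dir, sub("\\.jpg$", ".png", f))))
  }
  jpgs <- list.files(dir, pattern = "\\.jpg$")
  expect_setequal(jpgs, records$crop_file)

  # re-running reproduces identical CSV content and identical PNG bytes
  dir2 <- withr::local_tempdir()
  res2 <- emit_records(counted, sim$frames, NULL, dir2, run_id = "sc")
  expect_identical(res$records, res2$records)
  png1 <- sub("\\.jpg$", ".png", records$crop_file[1])
  expect_identical(readBin(file.path(dir, png1), "raw", 1e6),
                   readBin(file.path(dir2, png1), "raw", 1e6))
})

test_that("size fields in records are consistent with the measure module", {
  sc <- clean_scene()
  cfg <- sc$cfg; sim <- sc$sim
  counted <- count_events(
    track_particles(detect_frames(sim$frames, cfg$window)), cfg$window)
  dir <- withr::local_tempdir()
  records <- emit_records(counted, sim$frames, NULL, dir)$records
  expect_equal(records$size_um, records$size_px * cfg$pixel_scale_um)
  expect_equal(records$size_category,
               as.character(size_category(records$size_px)))
})

test_that("overlay draws the window everywhere and counters never decrease", {
  sc <- clean_scene()
  cfg <- sc$cfg; sim <- sc$sim
  counted <- count_events(
    track_particles(detect_frames(sim$frames, cfg$window)), cfg$window)
  dir <- withr::local_tempdir()
  records <- emit_records(counted, sim$frames, NULL, dir)$records
  sub <- frame_stack(sim$frames$frames[1:10], cfg$pixel_scale_um)
  ov <- overlay_video(sub, counted, records, cfg$window)
  expect_equal(length(ov), 10L)
  w <- cfg$window
  for (t in c(1, 5, 10)) {
    expect_true(all(ov[[t]][w$y0 + 1, (w$x0:(w$x0 + w$width - 1)) + 1] == 255))
  }
  # an empty run leaves frames unchanged except the window rectangle + counters
  ov0 <- overlay_video(sub, list(), flowmp:::empty_records(), w)
  diffpix <- sum(ov0[[1]] != sub$frames[[1]])
  expect_lt(diffpix, 2 * (w$width + w$height) + 60)
})
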