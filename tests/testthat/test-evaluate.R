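# Confusion summaries, detection efficiency, size histograms, geometry.

test_that("confusion summary reproduces the printed per-class rates", {
  # 24 of 25 grains correct (one grain evaluated as fiber), 25 of 25 fibers
  preds <- data.frame(
    label = c(rep("grain", 24), "fiber", rep("fiber", 25)),
    confidence_pct = rep(95, 50))
  truths <- c(rep("grain", 25), rep("fiber", 25))
  cs <- confusion_summary(preds, truths, confidence_threshold = 90)
  expect_equal(unname(cs$correct_rate_pct["grain"]), 96.0)
  expect_equal(unname(cs$correct_rate_pct["fiber"]), 100.0)
  expect_equal(cs$average_pct, 98.0)
  expect_equal(cs$counts["fiber", "grain"], 1L)
  expect_equal(cs$counts["grain", "grain"], 24L)
  expect_equal(sum(cs$counts), 50L)
})

test_that("confidence below the threshold makes a correct label incorrect", {
  preds <- data.frame(label = c("grain", "fiber"), confidence_pct = c(80, 80))
  cs <- confusion_summary(preds, c("grain", "fiber"))
  expect_equal(unname(cs$correct_rate_pct), c(0, 0))
  # but plain label agreement is still reported
  expect_equal(unname(cs$label_rate_pct), c(100, 100))
  # all confident and correct
  preds$confidence_pct <- c(100, 100)
  expect_equal(unname(confusion_summary(preds,
                                        c("grain", "fiber"))$correct_rate_pct),
               c(100, 100))
  expect_error(confusion_summary(data.frame(label = character(0),
                                            confidence_pct = numeric(0)),
                                 character(0)), "empty")
})

test_that("confusion summary is invariant to input ordering", {
  set.seed(8)
  n <- 40
  labels <- sample(c("grain", "fiber"), n, replace = TRUE)
  preds <- data.frame(label = sample(c("grain", "fiber"), n, replace = TRUE),
                      confidence_pct = runif(n, 60, 100))
  truths <- labels
  perm <- sample(n)
  a <- confusion_summary(preds, truths)
  b <- confusion_summary(preds[perm, ], truths[perm])
  expect_equal(a$correct_rate_pct, b$correct_rate_pct)
  expect_equal(a$counts, b$counts)
})

test_that("detection efficiency is the matched fraction of traversals", {
  # synthetic truth: 10 particles crossing; 8 records at matching positions
  traj <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(id = i, frame = 1:20, x = 8 * (0:19) + i, y = 10 * i)
  }))
  truth <- structure(list(trajectory = traj,
                          window = det_window(0, 0, 200, 200)),
                     class = "ground_truth")
  recs <- data.frame(frame = rep(10, 8), centroid_x = 8 * 9 + (1:8),
                     centroid_y = 10 * (1:8))
  eff <- detection_efficiency(recs, truth, max_dist = 5)
  expect_equal(eff$efficiency_pct, 80)
  expect_equal(eff$n_matched, 8L)
  expect_equal(eff$false_positives, 0L)
  expect_equal(sort(eff$merged_truth_ids), c(9L, 10L))
  # a far-away record is a false positive, never efficiency
  recs2 <- rbind(recs, data.frame(frame = 10, centroid_x = 500,
                                  centroid_y = 500))
  eff2 <- detection_efficiency(recs2, truth, max_dist = 5)
  expect_equal(eff2$efficiency_pct, 80)
  expect_equal(eff2$false_positives, 1L)
  expect_true(eff2$efficiency_pct >= 0 && eff2$efficiency_pct <= 100)
})

test_that("size histogram partitions the records", {
  sizes <- c(10, 60, 110, 260, 490, 700)
  h <- size_histogram(sizes)
  expect_equal(sum(h), length(sizes))
  expect_equal(unname(h[1]), 1L)            # [0, 50)
  expect_equal(unname(h[length(h)]), 1L)    # open-ended > 500
  expect_equal(sum(size_histogram(numeric(0))), 0L)
})

test_that("simulated grain sizes follow the configured lognormal", {
  set.seed(14)
  sizes <- flowmp:::rtrunc_lnorm(500, 152.9, 94.1, 36, 500)
  expect_lt(abs(mean(sizes) - 152.9) / 152.9, 0.12)
  # right-skew: mean above median, as in natural size distributions
  expect_gt(mean(sizes), median(sizes))
  h <- size_histogram(sizes)
  expect_equal(sum(h), 500L)
  expect_gt(which.max(h[1:10]), 1)   # mode above the first bin
})

test_that("field-of-view coverage reproduces the printed geometry", {
  expect_identical(fov_coverage(11.2, 12), 93.3)
  expect_identical(fov_coverage(12, 12), 100)
  expect_identical(fov_coverage(6, 12), 50)
  expect_error(fov_coverage(0, 12))
})
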