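# Independent brute-force oracles and shared fixtures for the test suite.

# O(n^2) maximum pairwise distance over the pixel-corner point set
oracle_feret_max <- function(pts) {
  cx <- c(pts[, 1] - 0.5, pts[, 1] + 0.5, pts[, 1] - 0.5, pts[, 1] + 0.5)
  cy <- c(pts[, 2] - 0.5, pts[, 2] - 0.5, pts[, 2] + 0.5, pts[, 2] + 0.5)
  best <- 0
  for (i in seq_along(cx)) {
    d <- sqrt((cx - cx[i])^2 + (cy - cy[i])^2)
    best <- max(best, max(d))
  }
  best
}

# brute-force 8-connected component labeling by repeated flood fill
oracle_label8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (y in seq_len(H)) for (x in seq_len(W)) {
    if (!mask[y, x] || lab[y, x] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(y, x))
    lab[y, x] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dy in -1:1) for (dx in -1:1) {
        yy <- p[1] + dy; xx <- p[2] + dx
        if (yy >= 1 && yy <= H && xx >= 1 && xx <= W &&
            mask[yy, xx] && lab[yy, xx] == 0L) {
          lab[yy, xx] <- nxt
          queue[[length(queue) + 1L]] <- c(yy, xx)
        }
      }
    }
  }
  lab
}

# minimal candidate data.frame for tracker tests
make_cand <- function(frame, cx, cy, feret = 10, area = 50) {
  data.frame(frame = as.integer(frame), cx = cx, cy = cy,
             bx0 = round(cx) - 2, by0 = round(cy) - 2, bw = 5L, bh = 5L,
             area_px = area, perimeter_px = 4 * sqrt(area),
             feret_h_px = feret, feret_v_px = feret / 2,
             feret_max_px = feret, feret_min_px = feret / 2,
             circularity = 0.7, aspect_ratio = 2,
             size_px = as.integer(round(feret)), size_um = round(feret) * 18)
}

# frame with one bright axis-aligned square
square_frame <- function(n = 40, x0 = 15, side = 10, value = 200) {
  fr <- matrix(0, n, n)
  fr[x0:(x0 + side - 1), x0:(x0 + side - 1)] <- value
  fr
}

# deterministic random binary frames for the region-extraction oracle
random_blob_frame <- function(seed, n = 48, n_blobs = 3) {
  set.seed(seed)
  fr <- matrix(0, n, n)
  for (b in seq_len(n_blobs)) {
    cx <- sample(8:(n - 8), 1); cy <- sample(8:(n - 8), 1)
    r <- sample(2:4, 1)
    xs <- matrix(rep(0:(n - 1), each = n), n, n)
    ys <- matrix(rep(0:(n - 1), times = n), n, n)
    fr[(xs - cx)^2 + (ys - cy)^2 < r^2] <- 200
  }
  fr
}

# small cached crop set + classifier shared by classify/report/pipeline tests
.test_cache <- new.env(parent = emptyenv())

tiny_crops <- function() {
  if (is.null(.test_cache$crops)) {
    .test_cache$crops <- simulate_crops(40, 40, seed = 421)
  }
  .test_cache$crops
}

tiny_model <- function() {
  if (is.null(.test_cache$model)) {
    sim <- tiny_crops()
    ts <- build_training_set(sim$crops, sim$labels, n_per_class = 30,
                             seed = 421)
    .test_cache$model <- train_classifier(ts, max_epochs = 20, seed = 421)
  }
  .test_cache$model
}

# small noise-free, non-touching benchmark scene used by several tests
clean_scene_config <- function(seed = 7) {
  scene_config(seed = seed, background_noise_sd = 0, n_distractors = 0,
               allow_touching = FALSE, n_grains = 5, n_fibers = 3,
               n_frames = 100)
}

clean_scene <- function() {
  if (is.null(.test_cache$scene)) {
    cfg <- clean_scene_config()
    .test_cache$scene <- list(cfg = cfg, sim = render_video(cfg))
  }
  .test_cache$scene
}
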