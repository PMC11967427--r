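# Synthetic flow-cell fluorescence video with exact ground truth.
#
# The simulator emulates bright stained particles advected through the field
# of view by a peristaltic pump with an intermittent (pulsed) drive: particles
# move a fixed number of pixels on "moving" frames and pause otherwise. Grain
# shapes are star-convex radial-harmonic polygons tuned by rejection sampling
# to hit circularity/aspect targets; fibers are thin curved strokes. Per-
# particle brightness, multiplicative intra-particle staining unevenness, a
# Gaussian point-spread blur and Gaussian background noise complete the image
# model. Everything is deterministic given the config seed.

#' Scene configuration for the synthetic flow-cell simulator
#'
#' Builds and validates the configuration consumed by [render_video()].
#' Grain shape defaults follow morphometry of natural sediment microplastics
#' (mean diameter 152.9 um, sd 94.1; circularity 0.42 sd 0.20; aspect ratio
#' 3.16 sd 1.51); sizes are drawn from a truncated lognormal matched to that
#' mean/sd.
#'
#' @param frame_width_px,frame_height_px frame size in pixels.
#' @param n_frames number of video frames.
#' @param pixel_scale_um micrometres per pixel (default 18).
#' @param n_grains,n_fibers number of grain / fiber particles.
#' @param grain_size_mean_um,grain_size_sd_um grain maximum-feret size
#'   distribution (um).
#' @param grain_circularity_mean,grain_circularity_sd circularity targets.
#' @param grain_aspect_mean,grain_aspect_sd aspect-ratio targets.
#' @param fiber_length_range_um,fiber_width_px_range fiber length (um) and
#'   stroke width (px) ranges.
#' @param flow_velocity_px_per_frame advection speed on moving frames.
#' @param pulsation_period_frames,pulsation_duty pump pulsation: within each
#'   period the first `duty` fraction of frames move, the rest pause.
#' @param staining_unevenness multiplicative intra-particle intensity
#'   variation in `[0, 1]` (0 = perfectly even staining).
#' @param background_noise_sd Gaussian background noise sd (8-bit units).
#' @param n_distractors number of dim out-of-focus non-plastic objects.
#' @param lateral_jitter_px sd of a small per-frame lateral (y) random walk;
#'   0 keeps trajectories perfectly parallel.
#' @param allow_touching if `FALSE`, initial placements are rejected until no
#'   two particle masks can ever overlap.
#' @param window detection window as returned by [det_window()]; defaults to
#'   a central band of the frame.
#' @param start_positions optional matrix/data.frame with columns x, y
#'   overriding random starting centroids (one row per particle, grains
#'   first, then fibers).
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(frame_width_px = 320, frame_height_px = 240,
                         n_frames = 120, pixel_scale_um = 18,
                         n_grains = 6, n_fibers = 3,
                         grain_size_mean_um = 152.9, grain_size_sd_um = 94.1,
                         grain_circularity_mean = 0.42,
                         grain_circularity_sd = 0.20,
                         grain_aspect_mean = 3.16, grain_aspect_sd = 1.51,
                         fiber_length_range_um = c(270, 1080),
                         fiber_width_px_range = c(1, 3),
                         flow_velocity_px_per_frame = 8,
                         pulsation_period_frames = 10, pulsation_duty = 0.6,
                         staining_unevenness = 0.3, background_noise_sd = 2,
                         n_distractors = 2, lateral_jitter_px = 0,
                         allow_touching = TRUE, window = NULL,
                         start_positions = NULL, seed = 1) {
  if (is.null(window)) {
    window <- det_window(round(0.4 * frame_width_px), 8,
                         round(0.3 * frame_width_px), frame_height_px - 16)
  }
  cfg <- list(
    frame_width_px = as.integer(frame_width_px),
    frame_height_px = as.integer(frame_height_px),
    n_frames = as.integer(n_frames),
    pixel_scale_um = pixel_scale_um,
    n_grains = as.integer(n_grains), n_fibers = as.integer(n_fibers),
    grain_size_mean_um = grain_size_mean_um,
    grain_size_sd_um = grain_size_sd_um,
    grain_circularity_mean = grain_circularity_mean,
    grain_circularity_sd = grain_circularity_sd,
    grain_aspect_mean = grain_aspect_mean,
    grain_aspect_sd = grain_aspect_sd,
    fiber_length_range_um = fiber_length_range_um,
    fiber_width_px_range = fiber_width_px_range,
    flow_velocity_px_per_frame = flow_velocity_px_per_frame,
    pulsation_period_frames = as.integer(pulsation_period_frames),
    pulsation_duty = pulsation_duty,
    staining_unevenness = staining_unevenness,
    background_noise_sd = background_noise_sd,
    n_distractors = as.integer(n_distractors),
    lateral_jitter_px = lateral_jitter_px,
    allow_touching = isTRUE(allow_touching),
    window = window,
    start_positions = start_positions,
    seed = as.integer(seed)
  )
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  stopifnot(
    cfg$frame_width_px > 0, cfg$frame_height_px > 0, cfg$n_frames > 0,
    cfg$pixel_scale_um > 0, cfg$n_grains >= 0, cfg$n_fibers >= 0,
    cfg$grain_size_mean_um > 0, cfg$grain_size_sd_um > 0,
    cfg$grain_circularity_mean > 0, cfg$grain_circularity_mean <= 1,
    cfg$grain_aspect_mean >= 1,
    cfg$flow_velocity_px_per_frame > 0,
    cfg$pulsation_period_frames >= 1,
    cfg$pulsation_duty > 0, cfg$pulsation_duty <= 1,
    cfg$staining_unevenness >= 0, cfg$staining_unevenness <= 1,
    cfg$background_noise_sd >= 0, cfg$n_distractors >= 0
  )
  w <- cfg$window
  if (w$width > cfg$frame_width_px || w$height > cfg$frame_height_px)
    stop("detection window larger than frame")
  if (w$x0 < 0 || w$y0 < 0 || w$x0 + w$width > cfg$frame_width_px ||
      w$y0 + w$height > cfg$frame_height_px)
    stop("detection window must fit inside the frame")
  invisible(cfg)
}

# evaluate code with a temporarily fixed RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rtrunc_lnorm <- function(n, mean, sd, lower, upper) {
  sdlog2 <- log(1 + (sd / mean)^2)
  meanlog <- log(mean) - sdlog2 / 2
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(2 * n + 10, meanlog, sqrt(sdlog2))
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n + 10, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Generate a grain-shaped binary mask
#'
#' Synthesizes a connected, star-convex particle mask whose measured maximum
#' feret, circularity and aspect ratio approximate the requested targets.
#' Shapes are radial-harmonic polygons
#' `r(theta) = R (1 + sum a_k cos(k theta + phi_k))`, anisotropically
#' stretched and randomly rotated, with the harmonic amplitude, stretch and
#' scale adapted by rejection sampling against measurements from
#' [shape_stats()].
#'
#' @param size_um target maximum feret diameter in micrometres (must be at
#'   least two pixels at `pixel_scale`).
#' @param circularity_target target circularity in (0, 1].
#' @param aspect_target target aspect ratio (>= 1).
#' @param pixel_scale micrometres per pixel.
#' @param seed optional integer seed (otherwise the current RNG stream is
#'   used).
#' @param max_tries rejection-sampling budget.
#' @param best_effort if `TRUE`, return the closest achieved shape instead of
#'   erroring when the target combination is unreachable at this resolution.
#' @return logical mask with attribute `"stats"` (its [shape_stats()] row).
#' @examples
#' m <- make_grain_mask(360, 1, 1, seed = 1)   # a disk of diameter 20 px
#' attr(m, "stats")
#' @export
make_grain_mask <- function(size_um, circularity_target, aspect_target,
                            pixel_scale = 18, seed = NULL, max_tries = 80,
                            best_effort = FALSE) {
  if (size_um < 2 * pixel_scale)
    stop("size_um must be at least 2 pixels at this pixel scale")
  if (circularity_target <= 0 || circularity_target > 1)
    stop("circularity_target must be in (0, 1]")
  if (aspect_target < 1) stop("aspect_target must be >= 1")
  run <- function() {
    feret_target <- size_um / pixel_scale
    # loose tolerances define acceptance; the loop keeps adapting toward the
    # tight ones so that population means stay close to the configured targets
    tol_circ <- 0.15; tol_aspect <- 0.5; tol_size <- 0.15
    tgt_circ <- 0.04; tgt_aspect <- 0.15; tgt_size <- 0.04
    best <- NULL; best_err <- Inf
    n_theta <- 96L
    theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
    tries <- 0L
    while (tries < max_tries) {
      # fresh harmonic draw; then adapt amp/stretch/scale against measurements
      amp <- max(0.02, 0.55 * (1 - circularity_target))
      stretch <- max(1, aspect_target)
      scale_px <- feret_target / 2
      ks <- 2:6
      u <- runif(length(ks), 0.3, 1)
      phi <- runif(length(ks), 0, 2 * pi)
      rot <- runif(1, 0, pi)
      for (it in seq_len(12L)) {
        tries <- tries + 1L
        if (tries > max_tries) break
        a <- amp * u / sqrt(ks)
        r <- 1 + as.vector(cos(outer(theta, ks) + rep(phi, each = n_theta)) %*% a)
        r <- pmax(r, 0.2)
        px <- stretch * r * cos(theta)
        py <- r * sin(theta)
        # rotate and scale
        xr <- scale_px * (px * cos(rot) - py * sin(rot))
        yr <- scale_px * (px * sin(rot) + py * cos(rot))
        pad <- 3
        xs <- xr - min(xr) + pad
        ys <- yr - min(yr) + pad
        W <- as.integer(ceiling(max(xs)) + pad)
        H <- as.integer(ceiling(max(ys)) + pad)
        mask <- .rasterize_polygon_cpp(xs, ys, W, H)
        if (sum(mask) < 3L) { scale_px <- scale_px * 1.5; next }
        mask <- largest_component(mask)
        st <- shape_stats(mask, pixel_scale)
        err <- abs(st$circularity - circularity_target) / tol_circ +
          abs(st$aspect_ratio - aspect_target) / tol_aspect +
          abs(st$feret_max_px - feret_target) / (tol_size * feret_target)
        if (err < best_err) { best <- list(mask = mask, st = st); best_err <- err }
        tight <- abs(st$circularity - circularity_target) <= tgt_circ &&
          abs(st$aspect_ratio - aspect_target) <= tgt_aspect &&
          abs(st$feret_max_px - feret_target) <= tgt_size * feret_target
        if (tight) {
          out <- mask
          attr(out, "stats") <- st
          return(out)
        }
        # multiplicative adaptation toward the targets
        scale_px <- scale_px * (feret_target / st$feret_max_px)^0.9
        stretch <- max(1, stretch * (aspect_target / st$aspect_ratio)^0.7)
        if (st$circularity > circularity_target + 0.02) {
          amp <- min(1.1, amp * 1.35)
        } else if (st$circularity < circularity_target - 0.02) {
          amp <- amp / 1.35
        }
      }
    }
    st <- best$st
    loose_ok <- abs(st$circularity - circularity_target) <= tol_circ &&
      abs(st$aspect_ratio - aspect_target) <= tol_aspect &&
      abs(st$feret_max_px - feret_target) <= tol_size * feret_target
    if (loose_ok || (best_effort && !is.null(best))) {
      out <- best$mask
      attr(out, "stats") <- best$st
      return(out)
    }
    stop(sprintf(
      paste0("unreachable shape targets (size %.1f um, circularity %.2f, ",
             "aspect %.2f); closest achieved: size %.1f um, circularity ",
             "%.2f, aspect %.2f"),
      size_um, circularity_target, aspect_target,
      st$feret_max_px * pixel_scale, st$circularity, st$aspect_ratio))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate a fiber-shaped binary mask
#'
#' Draws a thin curved stroke: a constant-step path whose heading turns by a
#' total of `curvature * pi` radians (plus mild wiggle), stamped with a
#' circular brush of the requested width.
#'
#' @param length_um fiber arc length in micrometres; must be at least
#'   `5 * width_px` pixels.
#' @param width_px stroke width in pixels.
#' @param curvature 0 (straight) to 1 (half-circle total turn).
#' @param pixel_scale micrometres per pixel.
#' @param seed optional integer seed.
#' @return logical mask with attribute `"stats"`.
#' @export
make_fiber_mask <- function(length_um, width_px = 2, curvature = 0.2,
                            pixel_scale = 18, seed = NULL) {
  L <- length_um / pixel_scale
  if (!is.finite(L) || L <= 0) stop("degenerate fiber length")
  if (L < 5 * width_px)
    stop("fiber length must be at least 5 times its width")
  run <- function() {
    step <- 0.4
    n <- max(3L, as.integer(ceiling(L / step)))
    heading0 <- runif(1, 0, 2 * pi)
    # total heading turn capped at a quarter circle so the stroke stays
    # clearly elongated (aspect ratio >= 4 for typical lengths)
    dturn <- curvature * (pi / 2) / n
    wig <- rnorm(n, 0, 0.2 * abs(dturn) + 0.002)
    headings <- heading0 + cumsum(rep(dturn, n) + wig)
    xs <- cumsum(step * cos(headings))
    ys <- cumsum(step * sin(headings))
    pad <- width_px + 2
    xs <- xs - min(xs) + pad
    ys <- ys - min(ys) + pad
    W <- as.integer(ceiling(max(xs)) + pad)
    H <- as.integer(ceiling(max(ys)) + pad)
    mask <- matrix(FALSE, H, W)
    # stamp width_px samples along the local perpendicular of the path
    perp_k <- seq_len(width_px) - (width_px + 1) / 2
    for (k in perp_k) {
      xi <- pmin(pmax(round(xs - k * sin(headings)), 0), W - 1)
      yi <- pmin(pmax(round(ys + k * cos(headings)), 0), H - 1)
      mask[cbind(yi + 1L, xi + 1L)] <- TRUE
    }
    mask <- largest_component(mask)
    out <- mask
    attr(out, "stats") <- shape_stats(mask, pixel_scale)
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

largest_component <- function(mask) {
  lab <- .label8_cpp(mask)
  if (max(lab) <= 1L) return(mask)
  tab <- tabulate(lab[lab > 0L])
  lab == which.max(tab)
}

# which frames move under the rectangular pulsation profile
pulse_moving <- function(frames, period, duty) {
  ((frames - 1L) %% period) < duty * period
}

#' Render a synthetic flow-cell video with ground truth
#'
#' Particles enter upstream of the detection window and advect left-to-right
#' at `flow_velocity_px_per_frame` on moving frames of the pulsation cycle.
#' Each particle carries a constant base brightness modulated by a smooth
#' multiplicative staining-unevenness field, the composited frame is blurred
#' by a small Gaussian point-spread function, and Gaussian background noise
#' is added before quantization to 8-bit. Distractors (dim, strongly
#' defocused non-plastic objects) are rendered at no more than 30% of the
#' particle brightness floor.
#'
#' @param config a [scene_config()].
#' @return list with `frames` (a `frame_stack`) and `truth` (a
#'   `ground_truth` list: `particles`, `trajectory`, `touching`,
#'   `distractors`).
#' @export
render_video <- function(config) {
  validate_scene_config(config)
  with_seed(config$seed, render_video_impl(config))
}

render_video_impl <- function(cfg) {
  W <- cfg$frame_width_px; H <- cfg$frame_height_px
  nf <- cfg$n_frames
  win <- cfg$window
  v <- cfg$flow_velocity_px_per_frame
  moving <- pulse_moving(seq_len(nf), cfg$pulsation_period_frames,
                         cfg$pulsation_duty)
  disp <- cumsum(ifelse(moving, v, 0))        # displacement after frame t
  n_par <- cfg$n_grains + cfg$n_fibers

  # --- particle shapes -------------------------------------------------------
  masks <- vector("list", n_par)
  classes <- character(n_par)
  if (cfg$n_grains > 0) {
    sizes <- rtrunc_lnorm(cfg$n_grains, cfg$grain_size_mean_um,
                          cfg$grain_size_sd_um,
                          2 * cfg$pixel_scale_um, 500)
    circs <- rtrunc_norm(cfg$n_grains, cfg$grain_circularity_mean,
                         cfg$grain_circularity_sd, 0.2, 0.9)
    asps <- rtrunc_norm(cfg$n_grains, cfg$grain_aspect_mean,
                        cfg$grain_aspect_sd, 1.1, 6)
    for (i in seq_len(cfg$n_grains)) {
      masks[[i]] <- make_grain_mask(sizes[i], circs[i], asps[i],
                                    cfg$pixel_scale_um, best_effort = TRUE)
      classes[i] <- "grain"
    }
  }
  if (cfg$n_fibers > 0) {
    lens <- runif(cfg$n_fibers, cfg$fiber_length_range_um[1],
                  cfg$fiber_length_range_um[2])
    wids <- sample(seq(cfg$fiber_width_px_range[1],
                       cfg$fiber_width_px_range[2]),
                   cfg$n_fibers, replace = TRUE)
    curvs <- runif(cfg$n_fibers, 0, 0.5)
    for (j in seq_len(cfg$n_fibers)) {
      lens[j] <- max(lens[j], 5 * wids[j] * cfg$pixel_scale_um)
      masks[[cfg$n_grains + j]] <-
        make_fiber_mask(lens[j], wids[j], curvs[j], cfg$pixel_scale_um)
      classes[cfg$n_grains + j] <- "fiber"
    }
  }

  # --- kinematics ------------------------------------------------------------
  # start positions: upstream of the window, far enough to fully traverse it
  radius <- vapply(masks, function(m) {
    max(attr(m, "stats")$feret_max_px / 2, 1)
  }, numeric(1))
  total_D <- if (nf > 0) disp[nf] else 0
  starts <- matrix(NA_real_, n_par, 2)
  if (!is.null(cfg$start_positions)) {
    sp <- as.matrix(cfg$start_positions)
    if (nrow(sp) != n_par) stop("start_positions must have one row per particle")
    starts <- sp[, 1:2, drop = FALSE]
  } else if (n_par > 0) {
    for (i in seq_len(n_par)) {
      r <- radius[i]
      hi <- win$x0 - r - 2
      lo <- max(win$x0 + win$width + r + 2 - total_D, hi - 0.6 * total_D)
      lo <- min(lo, hi)
      ymin <- win$y0 + r + 1
      ymax <- win$y0 + win$height - r - 2
      if (ymax < ymin) { ymin <- H / 2; ymax <- H / 2 }
      ok <- FALSE
      for (attempt in seq_len(200L)) {
        sx <- runif(1, lo, hi)
        sy <- runif(1, ymin, ymax)
        if (cfg$allow_touching) { ok <- TRUE } else {
          ok <- TRUE
          for (j in seq_len(i - 1L)) {
            if (abs(sx - starts[j, 1]) < radius[i] + radius[j] + 7 &&
                abs(sy - starts[j, 2]) < radius[i] + radius[j] + 7) {
              ok <- FALSE
              break
            }
          }
        }
        if (ok) { starts[i, ] <- c(sx, sy); break }
      }
      if (!ok) stop("could not place particles without touching")
    }
  }

  # lateral jitter path per particle (rounded random walk, integer offsets)
  jit <- matrix(0L, n_par, nf)
  if (cfg$lateral_jitter_px > 0 && n_par > 0 && nf > 1) {
    for (i in seq_len(n_par)) {
      walk <- cumsum(rnorm(nf, 0, cfg$lateral_jitter_px))
      jit[i, ] <- as.integer(round(walk - walk[1]))
    }
  }

  # integer stamping offsets: position of mask centroid at frame t
  cents <- lapply(masks, mask_centroid)
  # per-particle brightness and unevenness field
  bright <- if (n_par > 0) runif(n_par, 180, 240) else numeric(0)
  fields <- vector("list", n_par)
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (cfg$staining_unevenness > 0) {
      coarse <- matrix(runif(16, -1, 1), 4, 4)
      f <- resize_matrix(coarse, nrow(m), ncol(m))
      fields[[i]] <- pmax(1 + cfg$staining_unevenness * f, 0.15)
    } else {
      fields[[i]] <- matrix(1, nrow(m), ncol(m))
    }
  }

  # distractors: small dim disks, heavily defocused
  nd <- cfg$n_distractors
  if (nd > 0) {
    d_r <- sample(1:3, nd, replace = TRUE)
    d_bright <- runif(nd, 0.4, 1) * 0.3 * 180
    d_start <- cbind(runif(nd, -0.5 * total_D, W), runif(nd, 4, H - 5))
  }

  # --- ground truth ----------------------------------------------------------
  traj <- if (n_par > 0) {
    do.call(rbind, lapply(seq_len(n_par), function(i) {
      x0i <- round(starts[i, 1] - cents[[i]]["x"])
      y0i <- round(starts[i, 2] - cents[[i]]["y"])
      data.frame(id = i, frame = seq_len(nf),
                 x = x0i + c(0, disp)[seq_len(nf)] + cents[[i]]["x"],
                 y = y0i + jit[i, ] + cents[[i]]["y"])
    }))
  } else {
    data.frame(id = integer(0), frame = integer(0),
               x = numeric(0), y = numeric(0))
  }

  offsets <- vector("list", n_par)  # integer top-left stamp offsets per frame
  for (i in seq_len(n_par)) {
    x0i <- round(starts[i, 1] - cents[[i]]["x"])
    y0i <- round(starts[i, 2] - cents[[i]]["y"])
    offsets[[i]] <- cbind(x = x0i + c(0, disp)[seq_len(nf)],
                          y = y0i + jit[i, ])
  }

  # --- rendering -------------------------------------------------------------
  frames <- vector("list", nf)
  touching <- list()
  for (t in seq_len(nf)) {
    canvas <- matrix(6, H, W)
    boxes <- vector("list", n_par)
    for (i in seq_len(n_par)) {
      m <- masks[[i]]
      ox <- offsets[[i]][t, "x"]; oy <- offsets[[i]][t, "y"]
      st <- stamp_add(canvas, m * fields[[i]] * bright[i], ox, oy)
      canvas <- st$canvas
      boxes[[i]] <- st$box
    }
    canvas <- gblur_matrix(canvas, 0.8)
    if (nd > 0) {
      dcan <- matrix(0, H, W)
      for (k in seq_len(nd)) {
        dm <- disk_mask(2 * d_r[k], pad = 1)
        dx <- d_start[k, 1] + c(0, disp)[t]
        dy <- d_start[k, 2]
        st <- stamp_add(dcan, dm * d_bright[k], round(dx - (ncol(dm) - 1) / 2),
                        round(dy - (nrow(dm) - 1) / 2))
        dcan <- st$canvas
      }
      canvas <- canvas + gblur_matrix(dcan, 2.5)
    }
    if (cfg$background_noise_sd > 0)
      canvas <- canvas + matrix(rnorm(H * W, 0, cfg$background_noise_sd), H, W)
    frames[[t]] <- matrix(as.integer(pmin(pmax(round(canvas), 0), 255)), H, W)

    # touching events: pairwise stamped-mask overlap
    if (n_par > 1) {
      for (i in seq_len(n_par - 1L)) {
        for (j in seq((i + 1L), n_par)) {
          if (masks_overlap(masks[[i]], offsets[[i]][t, ],
                            masks[[j]], offsets[[j]][t, ])) {
            touching[[length(touching) + 1L]] <-
              data.frame(frame = t, id1 = i, id2 = j)
          }
        }
      }
    }
  }

  touching <- if (length(touching)) do.call(rbind, touching) else
    data.frame(frame = integer(0), id1 = integer(0), id2 = integer(0))

  particles <- if (n_par > 0) {
    do.call(rbind, lapply(seq_len(n_par), function(i) {
      st <- attr(masks[[i]], "stats")
      m <- masks[[i]]
      # frames in which the particle's bounding box lies fully in the window
      inside <- vapply(seq_len(nf), function(t) {
        ox <- offsets[[i]][t, "x"]; oy <- offsets[[i]][t, "y"]
        p <- mask_pixels(m)
        bx0 <- min(p[, 1]) + ox; bx1 <- max(p[, 1]) + ox
        by0 <- min(p[, 2]) + oy; by1 <- max(p[, 2]) + oy
        bx0 >= win$x0 && bx1 < win$x0 + win$width &&
          by0 >= win$y0 && by1 < win$y0 + win$height
      }, logical(1))
      data.frame(
        id = i, true_class = classes[i], true_size_um = st$size_um,
        true_size_px = st$size_px,
        true_circularity = st$circularity, true_aspect = st$aspect_ratio,
        first_frame_in_window = if (any(inside)) min(which(inside)) else NA,
        last_frame_in_window = if (any(inside)) max(which(inside)) else NA
      )
    }))
  } else {
    data.frame(id = integer(0), true_class = character(0),
               true_size_um = numeric(0), true_size_px = integer(0),
               true_circularity = numeric(0), true_aspect = numeric(0),
               first_frame_in_window = integer(0),
               last_frame_in_window = integer(0))
  }

  stack <- frame_stack(frames, cfg$pixel_scale_um)
  truth <- structure(list(particles = particles, trajectory = traj,
                          touching = touching, window = win),
                     class = "ground_truth")
  list(frames = stack, truth = truth)
}

stamp_add <- function(canvas, patch, ox, oy) {
  H <- nrow(canvas); W <- ncol(canvas)
  h <- nrow(patch); w <- ncol(patch)
  x0 <- max(0, ox); x1 <- min(W - 1, ox + w - 1)
  y0 <- max(0, oy); y1 <- min(H - 1, oy + h - 1)
  if (x0 > x1 || y0 > y1)
    return(list(canvas = canvas, box = NULL))
  canvas[(y0:y1) + 1L, (x0:x1) + 1L] <-
    canvas[(y0:y1) + 1L, (x0:x1) + 1L] +
    patch[(y0:y1) - oy + 1L, (x0:x1) - ox + 1L]
  list(canvas = canvas, box = c(x0, y0, x1, y1))
}

masks_overlap <- function(m1, o1, m2, o2) {
  p1 <- mask_pixels(m1)
  b1 <- c(min(p1[, 1]), min(p1[, 2]), max(p1[, 1]), max(p1[, 2])) +
    c(o1["x"], o1["y"], o1["x"], o1["y"])
  p2 <- mask_pixels(m2)
  b2 <- c(min(p2[, 1]), min(p2[, 2]), max(p2[, 1]), max(p2[, 2])) +
    c(o2["x"], o2["y"], o2["x"], o2["y"])
  if (b1[3] < b2[1] || b2[3] < b1[1] || b1[4] < b2[2] || b2[4] < b1[2])
    return(FALSE)
  k1 <- paste(p1[, 1] + o1["x"], p1[, 2] + o1["y"])
  k2 <- paste(p2[, 1] + o2["x"], p2[, 2] + o2["y"])
  any(k1 %in% k2)
}

gblur_matrix <- function(m, sigma) {
  as.matrix(EBImage::imageData(EBImage::gblur(m, sigma = sigma)))
}

resize_matrix <- function(m, nr, nc) {
  as.matrix(EBImage::imageData(EBImage::resize(m, w = nr, h = nc)))
}

#' Frame stack container
#'
#' @param frames list of integer matrices (rows y, columns x, 0-255).
#' @param pixel_scale_um micrometres per pixel.
#' @param frame_rate frames per second (informational, default 10).
#' @return object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_scale_um = 18, frame_rate = 10) {
  stopifnot(is.list(frames))
  if (length(frames)) {
    d <- dim(frames[[1]])
    ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
    if (!all(ok)) stop("all frames must share dimensions")
  }
  structure(list(frames = frames,
                 height = if (length(frames)) nrow(frames[[1]]) else 0L,
                 width = if (length(frames)) ncol(frames[[1]]) else 0L,
                 n_frames = length(frames),
                 pixel_scale_um = pixel_scale_um,
                 frame_rate = frame_rate),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("frame_stack: %d frames, %d x %d px, %.1f um/px\n",
              x$n_frames, x$width, x$height, x$pixel_scale_um))
  invisible(x)
}

#' Number of ground-truth particles that traversed the detection window
#'
#' A particle traverses the window when its true centroid lies inside the
#' window on at least one frame.
#'
#' @param truth ground truth from [render_video()].
#' @param window detection window ([det_window()]); defaults to the one the
#'   scene was rendered with.
#' @return integer count.
#' @export
truth_traversals <- function(truth, window = truth$window) {
  tr <- truth$trajectory
  if (!nrow(tr)) return(0L)
  inside <- tr$x >= window$x0 & tr$x < window$x0 + window$width &
    tr$y >= window$y0 & tr$y < window$y0 + window$height
  length(unique(tr$id[inside]))
}

#' Write a rendered scene to disk
#'
#' Frames are written as zero-padded numbered PNG files, ground truth as
#' plain CSV tables, and the scene configuration as YAML.
#'
#' @param sim result of [render_video()].
#' @param dir output directory (created if needed).
#' @param config the `scene_config` used (serialized alongside).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(sim, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fr <- sim$frames
  for (t in seq_len(fr$n_frames)) {
    EBImage::writeImage(t(fr$frames[[t]]) / 255,
                        file.path(dir, sprintf("frame_%05d.png", t)))
  }
  write.csv(sim$truth$particles, file.path(dir, "truth_particles.csv"),
            row.names = FALSE)
  write.csv(sim$truth$trajectory, file.path(dir, "truth_trajectory.csv"),
            row.names = FALSE)
  write.csv(sim$truth$touching, file.path(dir, "truth_touching.csv"),
            row.names = FALSE)
  if (!is.null(config)) {
    cfg <- config
    cfg$window <- unclass(cfg$window)
    cfg$start_positions <- NULL
    yaml::write_yaml(unclass(cfg), file.path(dir, "scene_config.yaml"))
  }
  invisible(dir)
}

#' Read a directory of frames into a frame stack
#'
#' Frames are read in lexicographic order from PNG/TIFF files; RGB input is
#' reduced to the green channel (the emission band of the stain falls in
#' green), or to luminance when `channel = "luminance"`.
#'
#' @param dir directory containing frame images.
#' @param pixel_scale_um micrometres per pixel.
#' @param channel `"green"` (default) or `"luminance"` for RGB input.
#' @param pattern filename regexp (default PNG/TIFF).
#' @return a [frame_stack()].
#' @export
read_frames <- function(dir, pixel_scale_um = 18,
                        channel = c("green", "luminance"),
                        pattern = "\\.(png|tif|tiff)$") {
  channel <- match.arg(channel)
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE,
                           ignore.case = TRUE))
  if (!length(files)) stop("no frame images found in ", dir)
  frames <- lapply(files, function(f) {
    img <- EBImage::readImage(f)
    d <- EBImage::imageData(img)
    if (length(dim(d)) == 3L) {
      d <- if (channel == "green") d[, , 2] else
        0.299 * d[, , 1] + 0.587 * d[, , 2] + 0.114 * d[, , 3]
    }
    matrix(as.integer(round(t(d) * 255)), ncol(d), nrow(d))
  })
  frame_stack(frames, pixel_scale_um)
}

#' Simulate labeled particle crops
#'
#' Generates isolated single-particle 100x100 crops with the same intensity
#' model as [render_video()], for classifier training and evaluation. Shape
#' defaults emulate mill-ground artificial microplastic fragments (compact,
#' moderately circular grains) plus laundry-derived fibers, the material used
#' to train and evaluate the shape classifier.
#'
#' @param n_grain,n_fiber number of crops per class.
#' @param pixel_scale_um micrometres per pixel.
#' @param grain_size_mean_um,grain_size_sd_um,grain_circularity_mean,grain_circularity_sd,grain_aspect_mean,grain_aspect_sd
#'   grain shape distribution (defaults: artificial ground fragments).
#' @param fiber_length_range_um,fiber_width_px_range fiber geometry.
#' @param staining_unevenness,background_noise_sd intensity model.
#' @param seed integer seed.
#' @return list with `crops` (list of 100x100 integer matrices), `labels`
#'   (factor grain/fiber) and `stats` (measured shape statistics).
#' @export
simulate_crops <- function(n_grain, n_fiber, pixel_scale_um = 18,
                           grain_size_mean_um = 290,
                           grain_size_sd_um = 130,
                           grain_circularity_mean = 0.60,
                           grain_circularity_sd = 0.15,
                           grain_aspect_mean = 2.2,
                           grain_aspect_sd = 0.8,
                           fiber_length_range_um = c(270, 1080),
                           fiber_width_px_range = c(1, 3),
                           staining_unevenness = 0.3,
                           background_noise_sd = 2, seed = 1) {
  with_seed(seed, {
    n <- n_grain + n_fiber
    crops <- vector("list", n)
    stats <- vector("list", n)
    labels <- c(rep("grain", n_grain), rep("fiber", n_fiber))
    if (n_grain > 0) {
      sizes <- rtrunc_lnorm(n_grain, grain_size_mean_um, grain_size_sd_um,
                            3 * pixel_scale_um, 500)
      circs <- rtrunc_norm(n_grain, grain_circularity_mean,
                           grain_circularity_sd, 0.25, 0.9)
      asps <- rtrunc_norm(n_grain, grain_aspect_mean, grain_aspect_sd,
                          1.1, 3.5)
    }
    if (n_fiber > 0) {
      lens <- runif(n_fiber, fiber_length_range_um[1],
                    fiber_length_range_um[2])
      wids <- sample(seq(fiber_width_px_range[1], fiber_width_px_range[2]),
                     n_fiber, replace = TRUE)
      curvs <- runif(n_fiber, 0, 0.5)
    }
    for (i in seq_len(n)) {
      if (i <= n_grain) {
        m <- make_grain_mask(sizes[i], circs[i], asps[i], pixel_scale_um,
                             best_effort = TRUE)
      } else {
        j <- i - n_grain
        lenj <- max(lens[j], 5 * wids[j] * pixel_scale_um)
        m <- make_fiber_mask(lenj, wids[j], curvs[j], pixel_scale_um)
      }
      stats[[i]] <- attr(m, "stats")
      bright <- runif(1, 180, 240)
      if (staining_unevenness > 0) {
        coarse <- matrix(runif(16, -1, 1), 4, 4)
        f <- pmax(1 + staining_unevenness *
                    resize_matrix(coarse, nrow(m), ncol(m)), 0.15)
      } else f <- matrix(1, nrow(m), ncol(m))
      patch <- m * f * bright
      canvas <- matrix(6, 100, 100)
      ph <- nrow(patch); pw <- ncol(patch)
      if (ph > 100 || pw > 100) {
        sc <- 96 / max(ph, pw)
        patch <- resize_matrix(patch, round(ph * sc), round(pw * sc))
        ph <- nrow(patch); pw <- ncol(patch)
      }
      oy <- as.integer(floor((100 - ph) / 2))
      ox <- as.integer(floor((100 - pw) / 2))
      canvas <- stamp_add(canvas, patch, ox, oy)$canvas
      canvas <- gblur_matrix(canvas, 0.8)
      if (background_noise_sd > 0)
        canvas <- canvas + matrix(rnorm(1e4, 0, background_noise_sd), 100, 100)
      crops[[i]] <- matrix(as.integer(pmin(pmax(round(canvas), 0), 255)),
                           100, 100)
    }
    list(crops = crops,
         labels = factor(labels, levels = c("grain", "fiber")),
         stats = do.call(rbind, stats))
  })
}
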