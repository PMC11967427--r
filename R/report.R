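# Assembly of counted tracks into particle records, crop files, the
# cross-referenceable CSV and the diagnostic overlay video.

RECORD_COLUMNS <- c("particle_id", "crop_file", "size_px", "size_um",
                    "size_category", "class", "confidence_pct", "frame",
                    "centroid_x", "centroid_y")

#' Emit particle records, crops and the run summary
#'
#' Writes one record per counted track: a JPEG crop (plus a lossless PNG
#' mirror) of the representative detection, and a CSV row with size, size
#' category, class and confidence. Classification uses the CNN `model` when
#' given, otherwise the rule-based rough classifier.
#'
#' @param counted result of [count_events()].
#' @param stack the [frame_stack()] the tracks came from.
#' @param model optional `mp_classifier`; `NULL` selects rough
#'   classification (confidence reported as `NA`).
#' @param outdir output directory (must be creatable/writable).
#' @param run_id prefix for crop file names.
#' @param pixel_scale micrometres per pixel (defaults to the stack's).
#' @return list with `records` (data.frame) and `summary` (list).
#' @export
emit_records <- function(counted, stack, model = NULL, outdir,
                         run_id = "run", pixel_scale = stack$pixel_scale_um) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  probe <- file.path(outdir, ".write_test")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE,
                 error = function(e) FALSE)
  if (!isTRUE(ok)) stop("output directory not writable: ", outdir)
  unlink(probe)

  n <- length(counted)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- counted[[i]]
    rep_row <- tr$representative
    frame <- stack$frames[[rep_row$frame]]
    crop <- extract_crop(frame, rep_row$cx, rep_row$cy, rep_row$feret_max_px)
    fname <- sprintf("%s_p%04d.jpg", run_id, tr$track_id)
    EBImage::writeImage(t(crop) / 255, file.path(outdir, fname), quality = 95)
    EBImage::writeImage(t(crop) / 255,
                        file.path(outdir, sub("\\.jpg$", ".png", fname)))
    if (is.null(model)) {
      lab <- rough_classify(rep_row)
      conf <- NA_real_
    } else {
      pred <- classify_crops(model, crop)
      lab <- pred$label
      conf <- pred$confidence_pct
    }
    rows[[i]] <- data.frame(
      particle_id = tr$track_id, crop_file = fname,
      size_px = rep_row$size_px,
      size_um = rep_row$size_px * pixel_scale,
      size_category = as.character(size_category(rep_row$size_px)),
      class = as.character(lab), confidence_pct = conf,
      frame = rep_row$frame,
      centroid_x = rep_row$cx, centroid_y = rep_row$cy
    )
  }
  records <- if (n > 0) do.call(rbind, rows) else empty_records()
  write.csv(records, file.path(outdir, sprintf("%s_records.csv", run_id)),
            row.names = FALSE)
  list(records = records,
       summary = run_summary(records, frames_processed = stack$n_frames,
                             frame_rate = stack$frame_rate))
}

empty_records <- function() {
  df <- data.frame(particle_id = integer(0), crop_file = character(0),
                   size_px = integer(0), size_um = numeric(0),
                   size_category = character(0), class = character(0),
                   confidence_pct = numeric(0), frame = integer(0),
                   centroid_x = numeric(0), centroid_y = numeric(0))
  stopifnot(identical(names(df), RECORD_COLUMNS))
  df
}

#' Run summary totals
#'
#' @param records a records data.frame from [emit_records()].
#' @param frames_processed number of frames analyzed.
#' @param frame_rate frames per second (for the informational particles/min).
#' @return list with `total_count`, `count_by_class`, `count_by_category`
#'   (per class), `frames_processed`, `particles_per_minute`.
#' @export
run_summary <- function(records, frames_processed = NA_integer_,
                        frame_rate = NA_real_) {
  lev <- size_category_levels()
  by_class <- vapply(CLASS_LEVELS, function(cl) sum(records$class == cl),
                     integer(1))
  by_cat <- lapply(CLASS_LEVELS, function(cl) {
    vapply(lev, function(cg)
      sum(records$class == cl & records$size_category == cg), integer(1))
  })
  names(by_cat) <- CLASS_LEVELS
  ppm <- if (is.finite(frames_processed) && is.finite(frame_rate) &&
             frames_processed > 0 && frame_rate > 0) {
    nrow(records) / (frames_processed / frame_rate / 60)
  } else NA_real_
  list(total_count = nrow(records), count_by_class = by_class,
       count_by_category = by_cat, frames_processed = frames_processed,
       particles_per_minute = ppm)
}

#' Annotate frames with detections and running counters
#'
#' Draws the detection window rectangle on every frame, circles counted
#' grains and boxes counted fibers at each frame where their track is
#' visible, and renders the frame number and cumulative count as small
#' bitmap digits in the top-left corner. Purely diagnostic.
#'
#' @param stack a [frame_stack()].
#' @param counted result of [count_events()].
#' @param records records from [emit_records()] (for class labels).
#' @param window a [det_window()].
#' @return list of annotated integer frame matrices.
#' @export
overlay_video <- function(stack, counted, records, window) {
  id2class <- setNames(records$class, records$particle_id)
  count_frame <- vapply(counted, function(tr) tr$representative$frame,
                        numeric(1))
  out <- vector("list", stack$n_frames)
  for (t in seq_len(stack$n_frames)) {
    fr <- stack$frames[[t]]
    fr <- draw_rect(fr, window$x0, window$y0,
                    window$x0 + window$width - 1,
                    window$y0 + window$height - 1, 255)
    for (tr in counted) {
      sel <- tr$cand$frame == t
      if (!any(sel)) next
      row <- tr$cand[which(sel)[1], ]
      cl <- id2class[[as.character(tr$track_id)]]
      r <- max(4, ceiling(row$feret_max_px / 2) + 2)
      if (identical(cl, "fiber")) {
        fr <- draw_rect(fr, round(row$cx) - r, round(row$cy) - r,
                        round(row$cx) + r, round(row$cy) + r, 255)
      } else {
        fr <- draw_circle(fr, row$cx, row$cy, r, 255)
      }
    }
    running <- sum(count_frame <= t)
    fr <- draw_number(fr, t, 2, 2, 255)
    fr <- draw_number(fr, running, 2, 10, 255)
    out[[t]] <- fr
  }
  out
}

draw_rect <- function(frame, x0, y0, x1, y1, value) {
  H <- nrow(frame); W <- ncol(frame)
  xs <- max(0, x0):min(W - 1, x1)
  ys <- max(0, y0):min(H - 1, y1)
  if (y0 >= 0 && y0 < H) frame[y0 + 1, xs + 1] <- value
  if (y1 >= 0 && y1 < H) frame[y1 + 1, xs + 1] <- value
  if (x0 >= 0 && x0 < W) frame[ys + 1, x0 + 1] <- value
  if (x1 >= 0 && x1 < W) frame[ys + 1, x1 + 1] <- value
  frame
}

draw_circle <- function(frame, cx, cy, r, value) {
  H <- nrow(frame); W <- ncol(frame)
  th <- seq(0, 2 * pi, length.out = max(16, ceiling(2 * pi * r)))
  xs <- round(cx + r * cos(th)); ys <- round(cy + r * sin(th))
  ok <- xs >= 0 & xs < W & ys >= 0 & ys < H
  frame[cbind(ys[ok] + 1, xs[ok] + 1)] <- value
  frame
}

# 3x5 bitmap digits
DIGIT_FONT <- lapply(list(
  c(7, 5, 5, 5, 7), c(2, 6, 2, 2, 7), c(7, 1, 7, 4, 7), c(7, 1, 7, 1, 7),
  c(5, 5, 7, 1, 1), c(7, 4, 7, 1, 7), c(7, 4, 7, 5, 7), c(7, 1, 1, 1, 1),
  c(7, 5, 7, 5, 7), c(7, 5, 7, 1, 7)
), function(rows) {
  do.call(rbind, lapply(rows, function(r) as.integer(intToBits(r)[3:1])))
})

draw_number <- function(frame, num, x, y, value) {
  digits <- strsplit(as.character(num), "")[[1]]
  for (d in digits) {
    glyph <- DIGIT_FONT[[as.integer(d) + 1L]]
    for (gy in 1:5) for (gx in 1:3) {
      if (glyph[gy, gx] == 1L) {
        yy <- y + gy; xx <- x + gx
        if (yy >= 1 && yy <= nrow(frame) && xx >= 1 && xx <= ncol(frame))
          frame[yy, xx] <- value
      }
    }
    x <- x + 4
  }
  frame
}
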