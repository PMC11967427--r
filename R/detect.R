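# Per-frame detection of bright particles with a Canny-style cascade:
# 5x5 Gaussian smoothing -> Sobel gradient -> non-maximum suppression ->
# hysteresis thresholding; closed contours are filled and measured.

#' Detection window
#'
#' Rectangular region of the frame, top-left origin, half-open
#' `[x0, x0 + width) x [y0, y0 + height)` in 0-based pixel coordinates.
#' Only candidates whose centroid falls inside the window are detected.
#'
#' @param x0,y0 top-left corner (0-based pixels).
#' @param width,height window extent in pixels (> 0).
#' @return object of class `det_window`.
#' @export
det_window <- function(x0, y0, width, height) {
  stopifnot(width > 0, height > 0, x0 >= 0, y0 >= 0)
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "det_window")
}

in_window <- function(x, y, window) {
  x >= window$x0 & x < window$x0 + window$width &
    y >= window$y0 & y < window$y0 + window$height
}

#' Detection parameters
#'
#' Hysteresis thresholds default to fractions of the frame's maximum gradient
#' magnitude (`high = high_frac * max`, `low = low_frac * high`), with an
#' absolute floor `min_gradient` so that blank frames yield no edges; they
#' can be fixed explicitly via `hysteresis_low` / `hysteresis_high`.
#'
#' @param hysteresis_low,hysteresis_high absolute gradient thresholds
#'   (`NULL` = derive from the frame, `0 < low < high`).
#' @param high_frac fraction of the maximum gradient used for the high
#'   threshold when not fixed. The default 0.1 keeps the faintest resolvable
#'   particle — a one-pixel-wide fiber at the brightness floor, attenuated by
#'   the point-spread blur — above the high threshold even when a bright
#'   saturated grain sets the frame maximum, while defocused distractors
#'   remain far below it.
#' @param low_frac low threshold as a fraction of the high one (default 0.4).
#' @param min_gradient absolute floor on the high threshold (8-bit gradient
#'   units, default 30). It anchors frames that contain no particle: there
#'   the maximum gradient comes from background noise alone and a purely
#'   relative threshold would collapse onto it. The default sits well above
#'   the noise-gradient ceiling of typical acquisitions (about 14 for
#'   noise sd 2 after smoothing) and far below the gradient of the faintest
#'   stained particle (over 100).
#' @param min_area_px minimum candidate area in pixels (default 1; one pixel
#'   is 18 um at the default scale).
#' @param fill_holes fill enclosed holes before measurement (default TRUE);
#'   uneven staining produces dark particle cores that must not split or
#'   hollow a detection.
#' @param close_gaps apply a 3x3 morphological closing to the edge mask
#'   before hole filling (default TRUE), so that 1-2 pixel breaks in a
#'   contour ring do not leave a particle unfilled or split.
#' @return object of class `det_params`.
#' @export
det_params <- function(hysteresis_low = NULL, hysteresis_high = NULL,
                       high_frac = 0.10, low_frac = 0.4, min_gradient = 30,
                       min_area_px = 1, fill_holes = TRUE, close_gaps = TRUE) {
  if (!is.null(hysteresis_low) && !is.null(hysteresis_high)) {
    stopifnot(hysteresis_low > 0, hysteresis_high > hysteresis_low)
  }
  stopifnot(high_frac > 0, high_frac < 1, low_frac > 0, low_frac <= 1,
            min_area_px >= 1)
  structure(list(hysteresis_low = hysteresis_low,
                 hysteresis_high = hysteresis_high,
                 high_frac = high_frac, low_frac = low_frac,
                 min_gradient = min_gradient,
                 min_area_px = as.integer(min_area_px),
                 fill_holes = isTRUE(fill_holes),
                 close_gaps = isTRUE(close_gaps)),
            class = "det_params")
}

#' Canny edge detection
#'
#' Runs the full cascade on a single-channel frame: 5x5 Gaussian smoothing,
#' Sobel first-derivative gradient (magnitude and direction), non-maximum
#' suppression along the gradient direction, and hysteresis thresholding
#' (pixels at or above the high threshold are kept; pixels at or above the
#' low threshold survive only when 8-connected to a kept pixel).
#'
#' @param frame numeric/integer matrix (rows y, columns x).
#' @param params a [det_params()].
#' @return logical edge mask of the same size.
#' @export
canny_edges <- function(frame, params = det_params()) {
  if (!is.matrix(frame) || length(frame) == 0L) stop("empty frame")
  storage.mode(frame) <- "double"
  sm <- .gauss5_cpp(frame)
  g <- .sobel_cpp(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  high <- params$hysteresis_high
  low <- params$hysteresis_low
  if (is.null(high)) {
    high <- max(params$high_frac * max(mag), params$min_gradient)
    low <- params$low_frac * high
  }
  supp <- .nms_cpp(mag, g$gx, g$gy)
  weak <- supp >= low & supp > 0
  if (!any(weak)) return(matrix(FALSE, nrow(frame), ncol(frame)))
  lab <- .label8_cpp(weak)
  strong_labs <- unique(lab[supp >= high & weak])
  strong_labs <- strong_labs[strong_labs > 0L]
  out <- matrix(lab %in% strong_labs, nrow(frame), ncol(frame))
  out
}

#' Extract particle candidates from an edge mask
#'
#' Closed contours are filled to regions (8-connected), regions smaller than
#' `min_area_px` are discarded, and only candidates whose centroid lies
#' inside the detection window are returned. Each candidate carries its
#' centroid, bounding box, area and full shape statistics.
#'
#' @param edges logical edge mask from [canny_edges()].
#' @param frame the source frame (same shape).
#' @param window a [det_window()].
#' @param params a [det_params()].
#' @param frame_index frame number recorded on each candidate.
#' @param pixel_scale micrometres per pixel.
#' @return data.frame of candidates (possibly 0 rows) with a `contour`
#'   list-column of boundary coordinates.
#' @export
extract_candidates <- function(edges, frame, window, params = det_params(),
                               frame_index = 1L, pixel_scale = 18) {
  if (!identical(dim(edges), dim(frame)))
    stop("edge mask and frame must have the same shape")
  work <- edges
  if (!is.null(params$close_gaps) && params$close_gaps)
    work <- erode3(.fill_holes_cpp(dilate3(work)))
  filled <- if (params$fill_holes) .fill_holes_cpp(work) else work
  lab <- .label8_cpp(filled)
  n <- max(lab)
  rows <- list()
  for (k in seq_len(n)) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < params$min_area_px) next
    xs <- idx[, 2] - 1L; ys <- idx[, 1] - 1L
    cx <- mean(xs); cy <- mean(ys)
    if (!in_window(cx, cy, window)) next
    bx0 <- min(xs); by0 <- min(ys)
    sub <- matrix(FALSE, max(ys) - by0 + 1L, max(xs) - bx0 + 1L)
    sub[cbind(ys - by0 + 1L, xs - bx0 + 1L)] <- TRUE
    st <- shape_stats(sub, pixel_scale)
    bnd <- boundary_pixels(sub)
    contour <- cbind(x = bnd[, 1] + bx0, y = bnd[, 2] + by0)
    row <- data.frame(frame = as.integer(frame_index), cx = cx, cy = cy,
                      bx0 = bx0, by0 = by0,
                      bw = ncol(sub), bh = nrow(sub), st)
    row$contour <- I(list(contour))
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) return(empty_candidates())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# 3x3 binary dilation / erosion via shifted copies
dilate3 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  out <- matrix(FALSE, H, W)
  for (dy in 0:2) for (dx in 0:2)
    out <- out | pad[(1:H) + dy, (1:W) + dx, drop = FALSE]
  out
}

erode3 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  out <- matrix(TRUE, H, W)
  for (dy in 0:2) for (dx in 0:2)
    out <- out & pad[(1:H) + dy, (1:W) + dx, drop = FALSE]
  out
}

empty_candidates <- function() {
  out <- data.frame(frame = integer(0), cx = numeric(0), cy = numeric(0),
                    bx0 = integer(0), by0 = integer(0),
                    bw = integer(0), bh = integer(0),
                    area_px = integer(0), perimeter_px = numeric(0),
                    feret_h_px = numeric(0), feret_v_px = numeric(0),
                    feret_max_px = numeric(0), feret_min_px = numeric(0),
                    circularity = numeric(0), aspect_ratio = numeric(0),
                    size_px = integer(0), size_um = numeric(0))
  out$contour <- I(list())
  out
}

#' Detect candidates on every frame of a stack
#'
#' @param stack a [frame_stack()].
#' @param window a [det_window()].
#' @param params a [det_params()].
#' @return list of candidate data.frames, one per frame.
#' @export
detect_frames <- function(stack, window, params = det_params()) {
  lapply(seq_len(stack$n_frames), function(t) {
    fr <- stack$frames[[t]]
    extract_candidates(canny_edges(fr, params), fr, window, params,
                       frame_index = t, pixel_scale = stack$pixel_scale_um)
  })
}
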