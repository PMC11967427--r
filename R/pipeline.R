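# End-to-end pipeline: detect -> track -> measure -> classify -> report,
# bound together by a serializable run configuration.

#' Run configuration
#'
#' @param input a [frame_stack()], or a directory of frame images.
#' @param outdir output directory.
#' @param pixel_scale_um micrometres per pixel.
#' @param window a [det_window()]; `NULL` derives a central band once the
#'   frame size is known.
#' @param detect a [det_params()].
#' @param link a [link_params()].
#' @param classifier `"rough"`, a model file path, or an `mp_classifier`.
#' @param run_id prefix for output file names.
#' @param frame_range optional `c(first, last)` subset of frames (pump-pulse
#'   trimming).
#' @param frame_stride keep every `frame_stride`-th frame (default 1).
#' @param overlay write annotated overlay frames (default FALSE).
#' @param seed integer seed recorded with the run.
#' @return object of class `run_config`.
#' @export
run_config <- function(input, outdir, pixel_scale_um = 18, window = NULL,
                       detect = det_params(), link = link_params(),
                       classifier = "rough", run_id = "run",
                       frame_range = NULL, frame_stride = 1L,
                       overlay = FALSE, seed = 1L) {
  structure(list(input = input, outdir = outdir,
                 pixel_scale_um = pixel_scale_um, window = window,
                 detect = detect, link = link, classifier = classifier,
                 run_id = run_id, frame_range = frame_range,
                 frame_stride = as.integer(frame_stride),
                 overlay = isTRUE(overlay), seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full detection pipeline
#'
#' Executes detection, tracking, measurement, classification and reporting
#' on a frame stack or frame directory, writing the records CSV, crops and
#' (optionally) overlay frames under `config$outdir`, along with the
#' serialized configuration.
#'
#' @param config a [run_config()].
#' @return list with `records`, `summary`, `tracks`, `counted`, `window` and
#'   the effective `config`.
#' @export
run_pipeline <- function(config) {
  stack <- config$input
  if (is.character(stack)) {
    if (!dir.exists(stack)) stop("unreadable input: ", stack)
    stack <- read_frames(stack, config$pixel_scale_um)
  }
  stopifnot(inherits(stack, "frame_stack"))
  if (!is.null(config$frame_range) || config$frame_stride > 1L) {
    idx <- seq_len(stack$n_frames)
    if (!is.null(config$frame_range))
      idx <- idx[idx >= config$frame_range[1] & idx <= config$frame_range[2]]
    idx <- idx[seq(1, length(idx), by = config$frame_stride)]
    stack <- frame_stack(stack$frames[idx], stack$pixel_scale_um,
                         stack$frame_rate)
  }
  window <- config$window
  if (is.null(window)) {
    window <- det_window(round(0.4 * stack$width), 8,
                         round(0.3 * stack$width), stack$height - 16)
  }
  model <- NULL
  if (inherits(config$classifier, "mp_classifier")) {
    model <- config$classifier
  } else if (is.character(config$classifier) &&
             !identical(config$classifier, "rough")) {
    if (!file.exists(config$classifier))
      stop("classifier model file not found: ", config$classifier,
           " (use classifier = \"rough\" for rule-based classification)")
    model <- load_classifier(config$classifier)
  }
  cands <- detect_frames(stack, window, config$detect)
  tracks <- track_particles(cands, config$link)
  counted <- count_events(tracks, window)
  res <- emit_records(counted, stack, model, config$outdir,
                      run_id = config$run_id)
  write_run_config(config, file.path(config$outdir,
                                     paste0(config$run_id, "_config.yaml")))
  if (config$overlay) {
    ov <- overlay_video(stack, counted, res$records, window)
    ovdir <- file.path(config$outdir, "overlay")
    dir.create(ovdir, showWarnings = FALSE)
    for (t in seq_along(ov)) {
      EBImage::writeImage(t(ov[[t]]) / 255,
                          file.path(ovdir, sprintf("overlay_%05d.png", t)))
    }
  }
  list(records = res$records, summary = res$summary, tracks = tracks,
       counted = counted, window = window, config = config)
}

#' Serialize / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$input <- if (is.character(x$input)) x$input else "<in-memory frames>"
  x$classifier <- if (is.character(x$classifier)) x$classifier
    else "<in-memory model>"
  x$window <- if (is.null(x$window)) NULL else unclass(x$window)
  x$detect <- unclass(x$detect)
  x$link <- unclass(x$link)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  win <- if (!is.null(x$window))
    det_window(x$window$x0, x$window$y0, x$window$width, x$window$height)
  run_config(
    input = x$input, outdir = x$outdir, pixel_scale_um = x$pixel_scale_um,
    window = win,
    detect = do.call(det_params, x$detect[setdiff(names(x$detect), NULL)]),
    link = do.call(link_params, x$link),
    classifier = x$classifier, run_id = x$run_id,
    frame_range = unlist(x$frame_range), frame_stride = x$frame_stride,
    overlay = x$overlay, seed = x$seed
  )
}
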