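# Performance quantification: per-class correct-answer rates, detection
# efficiency against ground truth, size distributions and geometry helpers.

#' Confusion summary with a confidence threshold
#'
#' Builds the evaluated-as x true-class matrix for grain/fiber predictions
#' and computes per-class correct-answer rates. A prediction is correct only
#' when the label matches the truth AND its confidence is at least
#' `confidence_threshold` percent; the plain label-agreement rates are
#' reported alongside.
#'
#' @param predictions data.frame with columns `label` and `confidence_pct`
#'   (as returned by [classify_crops()]), or a label vector (confidence then
#'   assumed 100).
#' @param truths true labels, same length.
#' @param confidence_threshold percent confidence required for a correct
#'   answer (default 90).
#' @return list of class `confusion_summary`: `counts` (matrix), per-class
#'   `correct_rate_pct`, `average_pct`, `label_rate_pct` (threshold-free),
#'   `n`.
#' @export
confusion_summary <- function(predictions, truths, confidence_threshold = 90) {
  if (is.data.frame(predictions)) {
    labels <- as.character(predictions$label)
    conf <- predictions$confidence_pct
  } else {
    labels <- as.character(predictions)
    conf <- rep(100, length(labels))
  }
  truths <- as.character(truths)
  if (!length(labels)) stop("empty input")
  if (length(labels) != length(truths)) stop("predictions/truths length mismatch")
  counts <- table(
    evaluated_as = factor(labels, levels = CLASS_LEVELS),
    true_class = factor(truths, levels = CLASS_LEVELS)
  )
  per_class <- vapply(CLASS_LEVELS, function(cl) {
    sel <- truths == cl
    if (!any(sel)) return(NA_real_)
    100 * sum(labels[sel] == cl & conf[sel] >= confidence_threshold) / sum(sel)
  }, numeric(1))
  label_rate <- vapply(CLASS_LEVELS, function(cl) {
    sel <- truths == cl
    if (!any(sel)) return(NA_real_)
    100 * sum(labels[sel] == cl) / sum(sel)
  }, numeric(1))
  structure(list(counts = unclass(counts),
                 correct_rate_pct = per_class,
                 average_pct = mean(per_class, na.rm = TRUE),
                 label_rate_pct = label_rate,
                 confidence_threshold = confidence_threshold,
                 n = length(labels)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("Confusion summary (evaluated-as x true-class):\n")
  print(x$counts)
  cat(sprintf("Correct-answer rates (confidence >= %g%%): %s\n",
              x$confidence_threshold,
              paste(sprintf("%s %.1f%%", names(x$correct_rate_pct),
                            x$correct_rate_pct), collapse = ", ")))
  cat(sprintf("Average: %.1f%%\n", x$average_pct))
  invisible(x)
}

#' Detection efficiency against ground truth
#'
#' Matches counted records to ground-truth particles: a record matches a
#' truth particle when its counted centroid lies within `max_dist` of that
#' particle's true trajectory position at the counted frame; matching is
#' one-to-one, greedy by distance. Efficiency is the percentage of
#' ground-truth particles that traversed the window recovered by distinct
#' records; over-counts are reported separately as a false-positive rate.
#'
#' @param records records data.frame from [emit_records()].
#' @param truth ground truth from [render_video()].
#' @param window detection window (defaults to the scene's).
#' @param max_dist matching radius in pixels (default 12, the default link
#'   distance).
#' @return list with `efficiency_pct`, `n_truth`, `n_matched`,
#'   `false_positives`, `false_positive_rate_pct`, `merged_truth_ids`
#'   (ground-truth particles not recovered).
#' @export
detection_efficiency <- function(records, truth, window = truth$window,
                                 max_dist = 12) {
  tr <- truth$trajectory
  inside <- tr$x >= window$x0 & tr$x < window$x0 + window$width &
    tr$y >= window$y0 & tr$y < window$y0 + window$height
  truth_ids <- unique(tr$id[inside])
  n_truth <- length(truth_ids)
  if (nrow(records) == 0L || n_truth == 0L) {
    return(list(efficiency_pct = if (n_truth == 0L) NA_real_ else 0,
                n_truth = n_truth, n_matched = 0L,
                false_positives = nrow(records),
                false_positive_rate_pct =
                  if (nrow(records)) 100 else 0,
                merged_truth_ids = truth_ids))
  }
  pairs <- list()
  for (r in seq_len(nrow(records))) {
    att <- tr[tr$frame == records$frame[r] & tr$id %in% truth_ids, ,
              drop = FALSE]
    if (!nrow(att)) next
    d <- sqrt((att$x - records$centroid_x[r])^2 +
                (att$y - records$centroid_y[r])^2)
    ok <- d <= max_dist
    if (any(ok)) {
      pairs[[length(pairs) + 1L]] <-
        data.frame(rec = r, id = att$id[ok], d = d[ok])
    }
  }
  matched_rec <- integer(0); matched_id <- integer(0)
  if (length(pairs)) {
    pairs <- do.call(rbind, pairs)
    pairs <- pairs[order(pairs$d, pairs$rec, pairs$id), , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      if (!(pairs$rec[k] %in% matched_rec) && !(pairs$id[k] %in% matched_id)) {
        matched_rec <- c(matched_rec, pairs$rec[k])
        matched_id <- c(matched_id, pairs$id[k])
      }
    }
  }
  n_matched <- length(matched_id)
  fp <- nrow(records) - n_matched
  list(efficiency_pct = 100 * n_matched / n_truth,
       n_truth = n_truth, n_matched = n_matched,
       false_positives = fp,
       false_positive_rate_pct = 100 * fp / nrow(records),
       merged_truth_ids = setdiff(truth_ids, matched_id))
}

#' Particle size histogram
#'
#' @param records records data.frame (uses `size_um`), or a numeric vector of
#'   sizes in micrometres.
#' @param bin_edges_um histogram bin edges (default 50-um bins, 0-500 um,
#'   with an open-ended final bin for anything larger).
#' @return named integer vector of counts per bin.
#' @export
size_histogram <- function(records, bin_edges_um = seq(0, 500, by = 50)) {
  sizes <- if (is.data.frame(records)) records$size_um else as.numeric(records)
  edges <- c(bin_edges_um, Inf)
  h <- table(cut(sizes, breaks = edges, right = FALSE))
  out <- as.integer(h)
  names(out) <- names(h)
  out
}

#' Field-of-view coverage of the flow-cell channel
#'
#' @param view_width_mm microscope field-of-view width (mm).
#' @param channel_width_mm flow-cell channel width (mm).
#' @return percentage, reported to one decimal.
#' @examples
#' fov_coverage(11.2, 12)   # 93.3
#' @export
fov_coverage <- function(view_width_mm, channel_width_mm) {
  stopifnot(view_width_mm > 0, channel_width_mm > 0)
  round(100 * view_width_mm / channel_width_mm, 1)
}
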