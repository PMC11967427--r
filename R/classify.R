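# Two-stage grain/fiber classification: a rule-based rough split on shape
# statistics, and a small CNN trained on 100x100 crops with mirror and
# 90-degree-rotation augmentation. Class order is fixed: grain = 0, fiber = 1.

CLASS_LEVELS <- c("grain", "fiber")

#' Rule-based rough classification
#'
#' Labels a particle as fiber when its aspect ratio is at least
#' `aspect_threshold` (default 4), or when it is both elongated (aspect >= 3)
#' and very non-circular (circularity < 0.2); otherwise grain. Natural grains
#' can be quite elongated (mean aspect ratio above 3), so the fiber gate is
#' deliberately stricter than that.
#'
#' @param stats a data.frame with columns `aspect_ratio` and `circularity`
#'   (e.g. from [shape_stats()] or candidate rows).
#' @param aspect_threshold fiber aspect-ratio gate (default 4).
#' @return factor vector with levels grain/fiber.
#' @export
rough_classify <- function(stats, aspect_threshold = 4) {
  fiber <- stats$aspect_ratio >= aspect_threshold |
    (stats$aspect_ratio >= 3 & stats$circularity < 0.2)
  factor(ifelse(fiber, "fiber", "grain"), levels = CLASS_LEVELS)
}

#' Extract a 100x100 crop around a detection
#'
#' The crop is centred on the candidate centroid. Particles larger than the
#' crop (maximum feret above 100 px) have their bounding region downscaled to
#' fit while preserving aspect ratio, padded with the local background level.
#'
#' @param frame integer/numeric frame matrix.
#' @param cx,cy centroid (0-based pixel coordinates).
#' @param feret_max_px the candidate's maximum feret (decides downscaling).
#' @param size crop side length (fixed at 100 for the classifier).
#' @return integer matrix `size x size`.
#' @export
extract_crop <- function(frame, cx, cy, feret_max_px = 0, size = 100) {
  H <- nrow(frame); W <- ncol(frame)
  bg <- as.numeric(stats::median(frame))
  half <- size / 2
  if (feret_max_px > size) {
    # downscale the (feret-sized) region to fit, preserving aspect
    r <- ceiling(feret_max_px / 2) + 4
    x0 <- round(cx) - r; x1 <- round(cx) + r
    y0 <- round(cy) - r; y1 <- round(cy) + r
    region <- matrix(bg, y1 - y0 + 1, x1 - x0 + 1)
    sx0 <- max(0, x0); sx1 <- min(W - 1, x1)
    sy0 <- max(0, y0); sy1 <- min(H - 1, y1)
    if (sx0 <= sx1 && sy0 <= sy1) {
      region[(sy0:sy1) - y0 + 1, (sx0:sx1) - x0 + 1] <-
        frame[(sy0:sy1) + 1, (sx0:sx1) + 1]
    }
    sc <- (size - 4) / max(dim(region))
    region <- resize_matrix(region, round(nrow(region) * sc),
                            round(ncol(region) * sc))
    out <- matrix(bg, size, size)
    oy <- floor((size - nrow(region)) / 2)
    ox <- floor((size - ncol(region)) / 2)
    out <- stamp_add(out, region - bg, ox, oy)$canvas
  } else {
    x0 <- round(cx) - half + 1; y0 <- round(cy) - half + 1
    out <- matrix(bg, size, size)
    sx0 <- max(0, x0); sx1 <- min(W - 1, x0 + size - 1)
    sy0 <- max(0, y0); sy1 <- min(H - 1, y0 + size - 1)
    if (sx0 <= sx1 && sy0 <= sy1) {
      out[(sy0:sy1) - y0 + 1, (sx0:sx1) - x0 + 1] <-
        frame[(sy0:sy1) + 1, (sx0:sx1) + 1]
    }
  }
  matrix(as.integer(round(pmin(pmax(out, 0), 255))), size, size)
}

# per-crop intensity normalization to [0, 1]
normalize_crop <- function(crop) {
  m <- as.numeric(crop)
  lo <- min(m); hi <- max(m)
  if (hi <= lo) return(matrix(0, nrow(crop), ncol(crop)))
  matrix((m - lo) / (hi - lo), nrow(crop), ncol(crop))
}

mirror_crop <- function(crop) crop[, rev(seq_len(ncol(crop))), drop = FALSE]
rot90_crop <- function(crop) t(crop)[, rev(seq_len(nrow(crop))), drop = FALSE]

#' Build an augmented, balanced training set
#'
#' Samples `n_per_class` crops per class without replacement, then augments
#' each with horizontal mirroring and all 90-degree rotations (8 orientations
#' per source image when both augmentations are on).
#'
#' @param crops list of 100x100 crop matrices.
#' @param labels factor/character vector of true labels (grain/fiber).
#' @param n_per_class images sampled per class before augmentation
#'   (default 250).
#' @param augment character subset of `c("mirror", "rot90")`.
#' @param seed integer seed for the per-class sampling.
#' @return list with `x` (list of matrices), `y` (factor), `meta`.
#' @export
build_training_set <- function(crops, labels, n_per_class = 250,
                               augment = c("mirror", "rot90"), seed = 1) {
  labels <- factor(as.character(labels), levels = CLASS_LEVELS)
  for (cl in CLASS_LEVELS) {
    n_avail <- sum(labels == cl)
    if (n_avail < n_per_class)
      stop(sprintf("not enough %s crops: %d available, %d required",
                   cl, n_avail, n_per_class))
  }
  sel <- with_seed(seed, {
    unlist(lapply(CLASS_LEVELS, function(cl) {
      sample(which(labels == cl), n_per_class)
    }))
  })
  x <- list(); y <- character(0)
  for (i in sel) {
    base <- crops[[i]]
    variants <- list(base)
    if ("mirror" %in% augment) variants <- c(variants, list(mirror_crop(base)))
    if ("rot90" %in% augment) {
      variants <- unlist(lapply(variants, function(v) {
        r1 <- rot90_crop(v); r2 <- rot90_crop(r1); r3 <- rot90_crop(r2)
        list(v, r1, r2, r3)
      }), recursive = FALSE)
    }
    x <- c(x, variants)
    y <- c(y, rep(as.character(labels[i]), length(variants)))
  }
  list(x = x, y = factor(y, levels = CLASS_LEVELS),
       meta = list(n_per_class = n_per_class, augment = augment, seed = seed,
                   n_images = length(x)))
}

#' Train the CNN shape classifier
#'
#' Trains a small convolutional network (three convolution blocks and a dense
#' head, built from scratch) on normalized 100x100 crops with mini-batch SGD.
#' Training stops early once the within-epoch training error rate drops below
#' `error_tol` (default 0.005), or after `max_epochs` epochs — in the latter
#' case the model is returned with a non-convergence warning flag.
#'
#' @param training_set result of [build_training_set()].
#' @param max_epochs maximum number of training passes (default 200).
#' @param seed integer seed controlling weight initialization and shuffling.
#' @param learning_rate,momentum,batch_size SGD hyper-parameters.
#' @param error_tol early-stopping training error rate.
#' @param min_epochs epochs trained before early stopping may trigger
#'   (default 10): continuing briefly past the error plateau sharpens the
#'   predicted class probabilities, which matter because evaluation requires
#'   at least 90% confidence for a correct answer.
#' @return object of class `mp_classifier`.
#' @export
train_classifier <- function(training_set, max_epochs = 200, seed = 1,
                             learning_rate = 0.01, momentum = 0.9,
                             batch_size = 32, error_tol = 0.005,
                             min_epochs = 10) {
  x <- training_set$x
  y <- training_set$y
  if (!length(x)) stop("empty training set")
  if (length(unique(y)) < 2L) stop("training set must contain both classes")
  X <- do.call(rbind, lapply(x, function(m) as.numeric(normalize_crop(m))))
  yi <- as.integer(y) - 1L   # grain = 0, fiber = 1
  fit <- .cnn_train_cpp(X, yi, as.integer(max_epochs), learning_rate,
                        momentum, as.integer(batch_size), error_tol,
                        as.integer(seed), as.integer(min(min_epochs, max_epochs)))
  if (!isTRUE(fit$converged))
    warning(sprintf("training did not reach error %.3f in %d epochs (final %.4f)",
                    error_tol, max_epochs, fit$final_error))
  structure(list(
    weights = fit[c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4",
                    "W5", "b5")],
    classes = CLASS_LEVELS,
    meta = list(n_train = as.list(table(y)), epochs = fit$epochs_run,
                max_epochs = max_epochs, seed = seed,
                augment = training_set$meta$augment,
                n_per_class = training_set$meta$n_per_class,
                final_error = fit$final_error,
                error_history = fit$error_history,
                converged = isTRUE(fit$converged))
  ), class = "mp_classifier")
}

#' @export
print.mp_classifier <- function(x, ...) {
  cat(sprintf(
    "mp_classifier: grain/fiber CNN, %d epochs, final training error %.4f%s\n",
    x$meta$epochs, x$meta$final_error,
    if (x$meta$converged) "" else " (not converged)"))
  invisible(x)
}

#' Classify particle crops
#'
#' @param model an `mp_classifier` from [train_classifier()].
#' @param crops a single 100x100 matrix or a list of them.
#' @return data.frame with `label` (factor grain/fiber) and `confidence_pct`
#'   (probability of the predicted class, 50-100).
#' @export
classify_crops <- function(model, crops) {
  if (is.matrix(crops)) crops <- list(crops)
  X <- do.call(rbind, lapply(crops, function(m) as.numeric(normalize_crop(m))))
  prob <- .cnn_predict_cpp(model$weights, X)
  idx <- max.col(prob, ties.method = "first")
  data.frame(
    label = factor(model$classes[idx], levels = model$classes),
    confidence_pct = 100 * prob[cbind(seq_len(nrow(prob)), idx)]
  )
}

#' Save / load a trained classifier
#'
#' The serialized model reloads with bit-identical predictions.
#'
#' @param model an `mp_classifier`.
#' @param path file path.
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   returns the model.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "mp_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mp_classifier")) stop("not a classifier model file")
  model
}
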