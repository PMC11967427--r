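# Cross-frame linking so each physical particle is counted exactly once.
#
# Matching is greedy nearest-predicted-neighbour with deterministic
# tie-breaks (smaller predicted distance, then smaller x, then smaller y),
# gated by displacement, lateral movement and frame-to-frame size ratio.

#' Linking parameters
#'
#' @param max_link_distance_px maximum distance between a candidate and the
#'   predicted position of a track (default 12).
#' @param expected_flow_dx_px signed expected per-frame displacement along
#'   the flow axis (default 8).
#' @param max_lateral_dy_px maximum lateral (y) movement per frame.
#' @param max_ratio_change largest allowed frame-to-frame ratio of maximum
#'   feret (applied symmetrically; default 2).
#' @param max_gap_frames number of missed frames a track survives before it
#'   is finalized (default 2, enough to bridge pump pauses).
#' @return object of class `link_params`.
#' @export
link_params <- function(max_link_distance_px = 12, expected_flow_dx_px = 8,
                        max_lateral_dy_px = 6, max_ratio_change = 2,
                        max_gap_frames = 2) {
  stopifnot(max_link_distance_px > 0, max_lateral_dy_px > 0,
            max_ratio_change >= 1, max_gap_frames >= 0)
  structure(list(max_link_distance_px = max_link_distance_px,
                 expected_flow_dx_px = expected_flow_dx_px,
                 max_lateral_dy_px = max_lateral_dy_px,
                 max_ratio_change = max_ratio_change,
                 max_gap_frames = as.integer(max_gap_frames)),
            class = "link_params")
}

#' Link candidates between two frames
#'
#' Computes a one-to-one partial matching between previous and current
#' candidates. Each previous candidate predicts its next position at
#' `(cx + elapsed * expected_flow_dx, cy)`; a current candidate may match
#' when its distance to the prediction is at most `max_link_distance_px`,
#' its lateral offset at most `max_lateral_dy_px`, and the feret ratio within
#' `[1/max_ratio_change, max_ratio_change]`. Pairs are accepted greedily by
#' increasing distance (ties: smaller current x, then y).
#'
#' @param prev,curr candidate data.frames (see [extract_candidates()]).
#' @param params a [link_params()].
#' @param elapsed frames elapsed between the two candidate sets (default 1;
#'   larger when bridging detection gaps).
#' @return integer vector of length `nrow(prev)`; entry i is the matched row
#'   in `curr` or `NA`.
#' @export
link_frames <- function(prev, curr, params = link_params(), elapsed = 1L) {
  np <- nrow(prev); nc <- nrow(curr)
  match_prev <- rep(NA_integer_, np)
  if (np == 0L || nc == 0L) return(match_prev)
  px <- prev$cx + elapsed * params$expected_flow_dx_px
  py <- prev$cy
  cand <- list()
  for (i in seq_len(np)) {
    dx <- curr$cx - px[i]
    dy <- curr$cy - py[i]
    d <- sqrt(dx^2 + dy^2)
    ratio <- curr$feret_max_px / prev$feret_max_px[i]
    ok <- d <= params$max_link_distance_px * elapsed &
      abs(dy) <= params$max_lateral_dy_px * elapsed &
      ratio >= 1 / params$max_ratio_change &
      ratio <= params$max_ratio_change
    if (any(ok)) {
      j <- which(ok)
      cand[[length(cand) + 1L]] <-
        data.frame(i = i, j = j, d = d[j], x = curr$cx[j], y = curr$cy[j])
    }
  }
  if (!length(cand)) return(match_prev)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$d, cand$x, cand$y, cand$i), , drop = FALSE]
  used_j <- logical(nc)
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (is.na(match_prev[i]) && !used_j[j]) {
      match_prev[i] <- j
      used_j[j] <- TRUE
    }
  }
  match_prev
}

#' Track particles across all frames
#'
#' Runs [link_frames()] frame by frame, starting new tracks for unmatched
#' candidates and aging unmatched tracks by one gap frame; a track is
#' finalized once its gap exceeds `max_gap_frames` or the video ends.
#'
#' @param candidates list of per-frame candidate data.frames (from
#'   [detect_frames()]).
#' @param params a [link_params()].
#' @return list of tracks; each track is a list with `track_id`, `cand` (the
#'   member candidates, ordered by frame), `first_frame`, `last_frame`.
#' @export
track_particles <- function(candidates, params = link_params()) {
  active <- list()
  done <- list()
  next_id <- 1L
  for (t in seq_along(candidates)) {
    curr <- candidates[[t]]
    if (length(active)) {
      prev <- do.call(rbind, lapply(active, function(tr) {
        utils::tail(tr$cand, 1)[, c("cx", "cy", "feret_max_px"), drop = FALSE]
      }))
      prev <- data.frame(prev,
                         elapsed = vapply(active, function(tr)
                           t - tr$last_frame, numeric(1)))
      # match per elapsed group so gap-bridged tracks predict farther ahead
      match <- rep(NA_integer_, nrow(prev))
      for (el in sort(unique(prev$elapsed))) {
        sel <- which(prev$elapsed == el)
        avail <- which(!seq_len(nrow(curr)) %in% match)
        if (!length(avail) || !nrow(curr)) break
        sub <- link_frames(prev[sel, , drop = FALSE],
                           curr[avail, , drop = FALSE], params,
                           elapsed = as.integer(el))
        match[sel] <- avail[sub]
      }
    } else {
      match <- integer(0)
    }
    new_active <- list()
    for (k in seq_along(active)) {
      tr <- active[[k]]
      if (length(match) >= k && !is.na(match[k])) {
        tr$cand <- rbind(tr$cand, curr[match[k], , drop = FALSE])
        tr$last_frame <- t
        tr$gap <- 0L
        new_active[[length(new_active) + 1L]] <- tr
      } else {
        tr$gap <- tr$gap + 1L
        if (tr$gap > params$max_gap_frames) {
          done[[length(done) + 1L]] <- tr
        } else {
          new_active[[length(new_active) + 1L]] <- tr
        }
      }
    }
    unmatched <- setdiff(seq_len(nrow(curr)), match[!is.na(match)])
    # deterministic creation order regardless of candidate ordering
    if (length(unmatched)) {
      ord <- unmatched[order(curr$cx[unmatched], curr$cy[unmatched])]
      for (j in ord) {
        new_active[[length(new_active) + 1L]] <-
          list(track_id = next_id, cand = curr[j, , drop = FALSE],
               first_frame = t, last_frame = t, gap = 0L)
        next_id <- next_id + 1L
      }
    }
    active <- new_active
  }
  done <- c(done, active)
  done <- done[order(vapply(done, function(tr) tr$track_id, integer(1)))]
  lapply(done, function(tr) {
    tr$gap <- NULL
    tr$cand <- tr$cand[order(tr$cand$frame), , drop = FALSE]
    rownames(tr$cand) <- NULL
    tr
  })
}

#' Select counting events from finished tracks
#'
#' Each track is counted exactly once, represented by its largest-area member
#' (the most in-focus, most fully stained view); ties take the earliest
#' frame. The count total is the number of tracks whose representative
#' centroid fell inside the detection window.
#'
#' @param tracks result of [track_particles()].
#' @param window a [det_window()].
#' @return list of counted tracks; each gains `representative` (one-row
#'   candidate data.frame) and `counted` (logical).
#' @export
count_events <- function(tracks, window) {
  out <- lapply(tracks, function(tr) {
    a <- tr$cand$area_px
    best <- which(a == max(a))[1]
    rep_row <- tr$cand[best, , drop = FALSE]
    tr$representative <- rep_row
    tr$counted <- in_window(rep_row$cx, rep_row$cy, window)
    tr
  })
  out[vapply(out, function(tr) isTRUE(tr$counted), logical(1))]
}
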