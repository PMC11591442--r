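# Track lifecycle: birth above the tracking threshold eta, a lost buffer
# during which the motion model keeps extrapolating, deletion once a track
# has been lost for more than `lost_buffer` frames, and linear interpolation
# of occlusion gaps as a post-processing step.

#' Create a tracker
#'
#' Returns a mutable tracker object (an environment) that [tracker_step()]
#' advances one frame at a time. Use [run_sequence()] for the common
#' whole-sequence case.
#'
#' @param th A [byte_thresholds()] object.
#' @param lost_buffer Frames a track may stay lost before deletion
#'   (default 30).
#' @param pars A [kf_pars()] object.
#' @param strict_reset If `TRUE`, a track that fails to match in a frame has
#'   its behavior counter zeroed (the literal reading of the counting
#'   procedure's reset branch). Default `FALSE`: counters persist and only a
#'   newly created track starts from zero.
#' @return An environment of class `byte_tracker`.
#' @export
byte_tracker <- function(th = byte_thresholds(), lost_buffer = 30L,
                         pars = kf_pars(), strict_reset = FALSE) {
  stopifnot(inherits(th, "byte_thresholds"), lost_buffer >= 1)
  e <- new.env(parent = emptyenv())
  e$th <- th
  e$lost_buffer <- as.integer(lost_buffer)
  e$pars <- pars
  e$strict_reset <- isTRUE(strict_reset)
  e$tracks <- list()
  e$next_id <- 1L
  e$last_frame <- 0L
  e$records <- vector("list", 256L)
  e$n_records <- 0L
  class(e) <- "byte_tracker"
  e
}

new_track <- function(id, frame, box, conf, cls, pars) {
  list(id = id, status = "active", kf = kf_init(box, pars),
       cls = cls, conf = conf, frames_lost = 0L,
       A = stats::setNames(integer(4), pig_classes()),
       start_frame = frame, end_frame = frame)
}

push_record <- function(e, frame, id, box, conf, cls) {
  e$n_records <- e$n_records + 1L
  if (e$n_records > length(e$records)) {
    length(e$records) <- 2L * length(e$records)
  }
  e$records[[e$n_records]] <- list(frame = frame, id = id, box = box,
                                   conf = conf, class = cls)
}

#' Advance the tracker by one frame
#'
#' Runs one full BYTE cycle: predict every non-removed track, associate in
#' two stages, update matched tracks (status active, class taken from the
#' matched detection, behavior counter incremented), spawn tracks from
#' stage-1 unmatched detections with confidence above `eta`, mark unmatched
#' tracks lost, and remove tracks lost for more than the lost buffer.
#'
#' @param tracker A [byte_tracker()].
#' @param frame Frame index; must be exactly one past the last processed
#'   frame.
#' @param dets Detection table for this frame (may have zero rows).
#' @return The tracker, invisibly.
#' @export
tracker_step <- function(tracker, frame, dets) {
  e <- tracker
  frame <- as.integer(frame)
  if (frame != e$last_frame + 1L) {
    stop(sprintf("out-of-order frame: expected %d, got %d",
                 e$last_frame + 1L, frame))
  }
  if (nrow(dets) && any(dets$frame != frame)) {
    stop("detections passed to tracker_step span more than one frame")
  }
  validate_detections(dets)

  live <- which(vapply(e$tracks, function(t) t$status != "removed", TRUE))
  for (i in live) e$tracks[[i]]$kf <- kf_predict(e$tracks[[i]]$kf, e$pars)

  det_boxes <- as.matrix(dets[, c("left", "top", "right", "bottom")])
  trk_boxes <- do.call(rbind, lapply(e$tracks[live],
                                     function(t) kf_box(t$kf)))
  if (is.null(trk_boxes)) trk_boxes <- matrix(numeric(), 0, 4)

  assoc <- byte_associate(trk_boxes, det_boxes, dets$conf, e$th)
  matches <- rbind(assoc$stage1$matches, assoc$stage2$matches)

  for (k in seq_len(nrow(matches))) {
    ti <- live[matches[k, "track"]]
    di <- matches[k, "detection"]
    trk <- e$tracks[[ti]]
    box <- det_boxes[di, ]
    trk$kf <- kf_update(trk$kf, box, e$pars)
    trk$status <- "active"
    trk$frames_lost <- 0L
    trk$cls <- dets$class[di]
    trk$conf <- dets$conf[di]
    trk$A <- accumulate_behavior(trk$A, encode_class(dets$class[di]))
    trk$end_frame <- frame
    e$tracks[[ti]] <- trk
    push_record(e, frame, trk$id, kf_box(trk$kf), trk$conf, trk$cls)
  }

  for (di in assoc$birth_candidates) {
    if (dets$conf[di] > e$th$eta) {
      trk <- new_track(e$next_id, frame, det_boxes[di, ],
                       dets$conf[di], dets$class[di], e$pars)
      trk$A <- accumulate_behavior(trk$A, encode_class(trk$cls))
      e$tracks[[length(e$tracks) + 1L]] <- trk
      e$next_id <- e$next_id + 1L
      push_record(e, frame, trk$id, det_boxes[di, ], trk$conf, trk$cls)
    }
  }

  for (li in assoc$unmatched_tracks) {
    ti <- live[li]
    trk <- e$tracks[[ti]]
    trk$status <- "lost"
    trk$frames_lost <- trk$frames_lost + 1L
    if (e$strict_reset) trk$A[] <- 0L
    if (trk$frames_lost > e$lost_buffer) trk$status <- "removed"
    e$tracks[[ti]] <- trk
  }

  e$last_frame <- frame
  invisible(e)
}

#' Collect a tracker's emitted records
#'
#' @param tracker A [byte_tracker()] after stepping.
#' @return Detection-table data frame of all matched rows (column `interp`
#'   all zero), sorted by frame.
#' @export
track_records <- function(tracker) {
  recs <- tracker$records[seq_len(tracker$n_records)]
  if (!length(recs)) return(empty_detections())
  out <- data.frame(
    frame = vapply(recs, `[[`, 0L, "frame"),
    id = vapply(recs, `[[`, 0L, "id"),
    left = vapply(recs, function(r) r$box[1], 0),
    top = vapply(recs, function(r) r$box[2], 0),
    right = vapply(recs, function(r) r$box[3], 0),
    bottom = vapply(recs, function(r) r$box[4], 0),
    conf = vapply(recs, `[[`, 0, "conf"),
    class = vapply(recs, `[[`, "", "class"),
    interp = 0L, stringsAsFactors = FALSE)
  out <- out[order(out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fill occlusion gaps of tracks by linear interpolation
#'
#' For every internal gap of a track bounded by matched entries at frames
#' `t1 < t2` with `t2 - t1 <= max_gap + 1`, inserts boxes
#' `B_t = B_t1 + (B_t2 - B_t1) * (t - t1) / (t2 - t1)` for `t1 < t < t2`,
#' flagged `interp = 1`. Endpoints are untouched, longer gaps are left
#' unfilled, and nothing is extrapolated outside a track's matched span.
#' Interpolated rows take the behavior class of the nearest matched endpoint
#' (the earlier one on ties) and a linearly interpolated confidence.
#'
#' @param records Detection-table data frame with track identities.
#' @param max_gap Longest gap (in missing frames) that is filled
#'   (default 20).
#' @return The records with interpolated rows inserted, sorted by frame.
#' @export
interpolate_tracks <- function(records, max_gap = 20L) {
  stopifnot(max_gap >= 1)
  validate_detections(records)
  if (!nrow(records)) return(records)
  if (!"interp" %in% names(records)) records$interp <- 0L
  pieces <- list(records)
  for (id in unique(records$id)) {
    h <- records[records$id == id & records$interp == 0L, , drop = FALSE]
    h <- h[order(h$frame), , drop = FALSE]
    if (nrow(h) < 2L) next
    for (k in seq_len(nrow(h) - 1L)) {
      t1 <- h$frame[k]; t2 <- h$frame[k + 1L]
      d <- t2 - t1
      if (d <= 1L || d > max_gap + 1L) next
      tt <- (t1 + 1L):(t2 - 1L)
      w <- (tt - t1) / d
      nearest_first <- w <= 0.5   # ties -> earlier endpoint
      pieces[[length(pieces) + 1L]] <- data.frame(
        frame = tt, id = id,
        left = h$left[k] + (h$left[k + 1L] - h$left[k]) * w,
        top = h$top[k] + (h$top[k + 1L] - h$top[k]) * w,
        right = h$right[k] + (h$right[k + 1L] - h$right[k]) * w,
        bottom = h$bottom[k] + (h$bottom[k + 1L] - h$bottom[k]) * w,
        conf = h$conf[k] + (h$conf[k + 1L] - h$conf[k]) * w,
        class = ifelse(nearest_first, h$class[k], h$class[k + 1L]),
        interp = 1L, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$frame, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Track a whole detection sequence
#'
#' Online BYTE pass over frames `1..n`, then (optionally) gap interpolation.
#' Returns every track ever created, including removed ones.
#'
#' @param dets Detection table for the full sequence (identities ignored).
#' @param th A [byte_thresholds()] object.
#' @param lost_buffer Lost-track deletion window in frames (default 30).
#' @param max_gap Longest interpolated gap in frames (default 20).
#' @param interpolate Apply gap interpolation (default `TRUE`).
#' @param n_frames Number of frames; defaults to the last detection's frame.
#' @param pars A [kf_pars()] object.
#' @param strict_reset See [byte_tracker()].
#' @return An object of class `pig_tracks`: list with `records` (per-frame
#'   rows incl. interpolated ones), `tracks` (one row per track: id, status,
#'   start/end frame, behavior frame counters) and the settings used.
#' @export
run_sequence <- function(dets, th = byte_thresholds(), lost_buffer = 30L,
                         max_gap = 20L, interpolate = TRUE,
                         n_frames = NULL, pars = kf_pars(),
                         strict_reset = FALSE) {
  validate_detections(dets)
  if (is.null(n_frames)) n_frames <- if (nrow(dets)) max(dets$frame) else 0L
  tr <- byte_tracker(th, lost_buffer, pars, strict_reset)
  by_frame <- split(seq_len(nrow(dets)), factor(dets$frame,
                                                levels = seq_len(n_frames)))
  for (f in seq_len(n_frames)) {
    tracker_step(tr, f, dets[by_frame[[f]], , drop = FALSE])
  }
  records <- track_records(tr)
  if (interpolate) records <- interpolate_tracks(records, max_gap)
  tracks <- do.call(rbind, lapply(tr$tracks, function(t) {
    data.frame(id = t$id, status = t$status, start_frame = t$start_frame,
               end_frame = t$end_frame,
               lie = t$A[["lie"]], stand = t$A[["stand"]],
               eat = t$A[["eat"]], other = t$A[["other"]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(tracks)) {
    tracks <- data.frame(id = integer(), status = character(),
                         start_frame = integer(), end_frame = integer(),
                         lie = integer(), stand = integer(), eat = integer(),
                         other = integer(), stringsAsFactors = FALSE)
  }
  structure(list(records = records, tracks = tracks, th = th,
                 lost_buffer = as.integer(lost_buffer),
                 max_gap = as.integer(max_gap),
                 interpolated = isTRUE(interpolate),
                 n_frames = as.integer(n_frames)),
            class = "pig_tracks")
}

#' @export
print.pig_tracks <- function(x, ...) {
  cat(sprintf("<pig_tracks> %d tracks over %d frames, %d rows (%d interpolated)\n",
              nrow(x$tracks), x$n_frames, nrow(x$records),
              sum(x$records$interp)))
  invisible(x)
}
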