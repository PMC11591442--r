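# Per-identity behavior time budgets: one-hot frame vectors, additive
# counters maintained on every successful match, and conversion from frame
# counts to seconds through the sequence frame rate.

#' One-hot encode a behavior class
#'
#' @param cls A behavior class name.
#' @return Named integer 4-vector over `(lie, stand, eat, other)` with a
#'   single 1 in the class's slot.
#' @export
encode_class <- function(cls) {
  classes <- pig_classes()
  if (length(cls) != 1L || !cls %in% classes) {
    stop("unknown behavior class: ", paste(cls, collapse = ", "))
  }
  stats::setNames(as.integer(classes == cls), classes)
}

#' Accumulate a frame's behavior vector into a track counter
#'
#' Componentwise addition `A + a`; called once per successful match of a
#' track in a frame.
#'
#' @param A Integer 4-vector counter.
#' @param a One-hot frame vector from [encode_class()].
#' @return The updated counter.
#' @export
accumulate_behavior <- function(A, a) {
  stopifnot(length(A) == 4L, length(a) == 4L)
  A + a
}

#' Behavior time budget per track
#'
#' Converts per-class matched-frame counts to seconds by dividing by the
#' frame rate. For a `pig_tracks` object the counters maintained online by
#' the tracker are used; for a plain records table (e.g. a re-read track
#' file) frames are counted per class over non-interpolated rows, which is
#' equivalent under the default counting rules.
#'
#' @param x A `pig_tracks` object from [run_sequence()], or a detection-table
#'   data frame with identities.
#' @param meta A [seq_meta()] (source of `fps`), or a number taken as fps.
#' @param count_interpolated Count interpolated rows too (only meaningful for
#'   records input; default `FALSE`, matching the tracker's rule that only
#'   detector-matched frames enter the counters).
#' @return Data frame of class `behavior_summary` with columns `track_id`,
#'   `<class>_frames` and `<class>_s` for the four classes, plus an `fps`
#'   attribute.
#' @export
behavior_summary <- function(x, meta, count_interpolated = FALSE) {
  fps <- if (inherits(meta, "seq_meta")) meta$fps else as.numeric(meta)
  stopifnot(length(fps) == 1L, fps > 0)
  classes <- pig_classes()
  if (inherits(x, "pig_tracks")) {
    frames <- as.matrix(x$tracks[, classes, drop = FALSE])
    ids <- x$tracks$id
  } else {
    validate_detections(x)
    if (nrow(x) && any(x$id < 0)) {
      stop("behavior summary needs identity-labeled rows (id >= 0)")
    }
    use <- if (count_interpolated || !"interp" %in% names(x)) x
           else x[x$interp == 0L, , drop = FALSE]
    ids <- sort(unique(x$id))
    frames <- t(vapply(ids, function(i) {
      tab <- table(factor(use$class[use$id == i], levels = classes))
      as.integer(tab)
    }, integer(4)))
    colnames(frames) <- classes
  }
  out <- data.frame(track_id = ids, frames, frames / fps,
                    stringsAsFactors = FALSE)
  names(out) <- c("track_id", paste0(classes, "_frames"),
                  paste0(classes, "_s"))
  rownames(out) <- NULL
  attr(out, "fps") <- fps
  class(out) <- c("behavior_summary", "data.frame")
  out
}

#' Write a behavior summary CSV
#'
#' @param summary A [behavior_summary()].
#' @param path Output path.
#' @export
write_behavior_summary <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE)
  invisible(path)
}

#' Grouped bar chart of behavior frame counts
#'
#' One group of four color-coded bars per track id, y = frames per class;
#' a CSV twin of the plotted numbers is written next to the image.
#'
#' @param summary A [behavior_summary()].
#' @param path Output image path (extension selects the device via
#'   [ggplot2::ggsave()]).
#' @param csv_path Path for the CSV twin; defaults to `path` with a `.csv`
#'   extension.
#' @return The ggplot object, invisibly.
#' @export
plot_behavior_histogram <- function(summary, path,
                                    csv_path = sub("\\.[^.]+$", ".csv", path)) {
  stopifnot(inherits(summary, "behavior_summary"), nrow(summary) > 0)
  classes <- pig_classes()
  long <- do.call(rbind, lapply(classes, function(cl) {
    data.frame(track_id = factor(summary$track_id),
               class = cl, frames = summary[[paste0(cl, "_frames")]],
               stringsAsFactors = FALSE)
  }))
  long$class <- factor(long$class, levels = classes)
  p <- ggplot2::ggplot(long,
         ggplot2::aes(x = track_id, y = frames, fill = class)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::scale_fill_manual(values = c(lie = "#1f3c88", stand = "#74b9e7",
                                          eat = "#d7263d", other = "#f4b942")) +
    ggplot2::labs(x = "track id", y = "frames", fill = "behavior") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 7, height = 4, dpi = 150)
  utils::write.csv(
    data.frame(track_id = summary$track_id,
               summary[, paste0(classes, "_frames")]),
    csv_path, row.names = FALSE)
  invisible(p)
}
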