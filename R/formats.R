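# MOT-dialect CSV I/O and the package-wide coordinate / class conventions.
#
# On disk boxes are (left, top, width, height) in pixels, MOTChallenge style;
# in memory they are corner pairs (left, top, right, bottom) with the origin
# at the top-left of the frame and frames numbered from 1.

#' Behavior classes
#'
#' The closed set of behavior classes, in the canonical slot order used by
#' every counter, file and plot in the package.
#'
#' @return Character vector `c("lie", "stand", "eat", "other")`.
#' @export
pig_classes <- function() c("lie", "stand", "eat", "other")

#' Default on-disk class codes
#'
#' Integer codes used in CSV files for the behavior classes. The mapping is
#' a convention of this package (codes are not fixed by the MOT dialect) and
#' every reader/writer accepts an alternative named vector.
#'
#' @return Named integer vector mapping class name to code.
#' @export
default_class_map <- function() {
  c(lie = 1L, stand = 2L, eat = 3L, other = 4L)
}

#' Sequence metadata
#'
#' @param name Sequence label.
#' @param fps Frames per second (> 0).
#' @param n_frames Number of frames (>= 1).
#' @param image_width,image_height Frame size in pixels.
#' @return An object of class `seq_meta`.
#' @export
seq_meta <- function(name = "seq", fps = 5, n_frames = 300L,
                     image_width = 1280L, image_height = 720L) {
  stopifnot(is.numeric(fps), length(fps) == 1L, fps > 0)
  n_frames <- as.integer(n_frames)
  stopifnot(n_frames >= 1L, image_width > 0, image_height > 0)
  structure(list(name = as.character(name), fps = as.numeric(fps),
                 n_frames = n_frames,
                 image_width = as.integer(image_width),
                 image_height = as.integer(image_height)),
            class = "seq_meta")
}

#' @export
print.seq_meta <- function(x, ...) {
  cat(sprintf("<seq_meta> %s: %d frames @ %g fps, %dx%d px\n",
              x$name, x$n_frames, x$fps, x$image_width, x$image_height))
  invisible(x)
}

#' Read a sequence metadata sidecar (YAML)
#'
#' @param path Path to a YAML file with keys `name`, `fps`, `n_frames`,
#'   `imWidth`, `imHeight`.
#' @return A [seq_meta()] object.
#' @export
read_seq_meta <- function(path) {
  y <- yaml::read_yaml(path)
  seq_meta(name = y$name %||% "seq", fps = y$fps, n_frames = y$n_frames,
           image_width = y$imWidth, image_height = y$imHeight)
}

#' Write a sequence metadata sidecar (YAML)
#'
#' @param meta A [seq_meta()] object.
#' @param path Output path.
#' @export
write_seq_meta <- function(meta, path) {
  stopifnot(inherits(meta, "seq_meta"))
  yaml::write_yaml(list(name = meta$name, fps = meta$fps,
                        n_frames = meta$n_frames,
                        imWidth = meta$image_width,
                        imHeight = meta$image_height), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a detection table's invariants; internal, called by readers and
# by functions that accept user-built data frames.
validate_detections <- function(x, require_class = TRUE) {
  need <- c("frame", "id", "left", "top", "right", "bottom", "conf")
  if (require_class) need <- c(need, "class")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("detection table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(x)) {
    if (any(!is.finite(x$left) | !is.finite(x$top) |
            !is.finite(x$right) | !is.finite(x$bottom))) {
      stop("non-finite box coordinate in detection table")
    }
    if (any(x$right <= x$left) || any(x$bottom <= x$top)) {
      stop("degenerate box: right <= left or bottom <= top")
    }
    if (any(x$conf < 0 | x$conf > 1)) {
      stop("confidence outside [0, 1]")
    }
    if (require_class && !all(x$class %in% pig_classes())) {
      bad <- unique(x$class[!x$class %in% pig_classes()])
      stop("unknown behavior class: ", paste(bad, collapse = ", "))
    }
  }
  invisible(x)
}

empty_detections <- function() {
  data.frame(frame = integer(), id = integer(), left = numeric(),
             top = numeric(), right = numeric(), bottom = numeric(),
             conf = numeric(), class = character(), interp = integer(),
             stringsAsFactors = FALSE)
}

#' Read a MOT-dialect CSV detection / ground-truth / track file
#'
#' Rows are `frame,id,bb_left,bb_top,bb_width,bb_height,conf,class[,interp]`
#' without a header. Width/height are converted to corner coordinates
#' (`right = left + width`, `bottom = top + height`). Identity `-1` marks a
#' detection without an identity. Boxes are not clipped to the image; see
#' [clip_boxes()] for that as an explicit step.
#'
#' @param path Path to the CSV file.
#' @param has_class If `TRUE` (default) column 8 holds a behavior class code.
#' @param class_map Named integer vector mapping class names to file codes.
#' @return A data frame with columns `frame`, `id`, `left`, `top`, `right`,
#'   `bottom`, `conf`, `class`, `interp`, sorted by frame (stable in file
#'   order within a frame).
#' @export
read_mot_file <- function(path, has_class = TRUE,
                          class_map = default_class_map()) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_detections())
  parts <- strsplit(lines, ",", fixed = TRUE)
  min_fields <- if (has_class) 8L else 7L
  nf <- lengths(parts)
  if (any(nf < min_fields)) {
    stop(sprintf("malformed row at line %d of %s: expected >= %d fields, got %d",
                 which(nf < min_fields)[1L], path, min_fields,
                 nf[which(nf < min_fields)[1L]]))
  }
  num <- function(k) {
    v <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", k)))
    if (anyNA(v)) {
      stop(sprintf("malformed row at line %d of %s: non-numeric field %d",
                   which(is.na(v))[1L], path, k))
    }
    v
  }
  frame <- num(1L); id <- num(2L)
  left <- num(3L); top <- num(4L); w <- num(5L); h <- num(6L)
  conf <- num(7L)
  if (any(w <= 0 | h <= 0)) {
    stop(sprintf("invalid box at line %d of %s: width/height must be positive",
                 which(w <= 0 | h <= 0)[1L], path))
  }
  if (any(conf < 0 | conf > 1)) {
    stop(sprintf("invalid confidence at line %d of %s: outside [0, 1]",
                 which(conf < 0 | conf > 1)[1L], path))
  }
  cls <- if (has_class) {
    code <- as.integer(num(8L))
    unknown <- setdiff(code, unname(class_map))
    if (length(unknown)) {
      stop("unknown class code in ", path, ": ",
           paste(unknown, collapse = ", "))
    }
    names(class_map)[match(code, class_map)]
  } else {
    rep(NA_character_, length(frame))
  }
  interp_col <- if (has_class) 9L else 8L
  interp <- if (all(nf >= interp_col)) as.integer(num(interp_col))
            else integer(length(frame)) # absent column: nothing interpolated
  out <- data.frame(frame = as.integer(frame), id = as.integer(id),
                    left = left, top = top, right = left + w,
                    bottom = top + h, conf = conf, class = cls,
                    interp = interp, stringsAsFactors = FALSE)
  out <- out[order(out$frame), , drop = FALSE]   # stable: keeps file order
  rownames(out) <- NULL
  validate_detections(out, require_class = has_class)
  out
}

#' Write tracker output as a MOT-dialect CSV
#'
#' One row per (track, frame):
#' `frame,id,left,top,width,height,conf,class_code,interp`. Coordinates are
#' written with two decimals, so a read/write round trip preserves boxes to
#' 2 dp. An empty track table yields an empty, header-free file.
#'
#' @param x Track records: a data frame as returned by [run_sequence()]
#'   (`$records`) or [read_mot_file()].
#' @param path Output path.
#' @param class_map Named integer vector mapping class names to file codes.
#' @export
write_track_file <- function(x, path, class_map = default_class_map()) {
  if (inherits(x, "pig_tracks")) x <- x$records
  validate_detections(x)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  if (!nrow(x)) return(invisible(path))
  x <- x[order(x$frame), , drop = FALSE]
  interp <- if ("interp" %in% names(x)) as.integer(x$interp)
            else integer(nrow(x))
  rows <- sprintf("%d,%d,%.2f,%.2f,%.2f,%.2f,%.6f,%d,%d",
                  x$frame, x$id, x$left, x$top,
                  x$right - x$left, x$bottom - x$top,
                  x$conf, unname(class_map[x$class]), interp)
  writeLines(rows, con)
  invisible(path)
}

#' Clip boxes to the image bounds
#'
#' Reading never clips (simulated pigs may straddle pen edges); this applies
#' clipping as an explicit step, dropping boxes left degenerate by it.
#'
#' @param x Detection table.
#' @param meta A [seq_meta()] with the image size.
#' @return The clipped table.
#' @export
clip_boxes <- function(x, meta) {
  stopifnot(inherits(meta, "seq_meta"))
  x$left <- pmax(x$left, 0); x$top <- pmax(x$top, 0)
  x$right <- pmin(x$right, meta$image_width)
  x$bottom <- pmin(x$bottom, meta$image_height)
  keep <- x$right > x$left & x$bottom > x$top
  x[keep, , drop = FALSE]
}
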