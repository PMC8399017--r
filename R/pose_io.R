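# Reading, validating and windowing BODY_25 pose key-point streams.
#
# A pose sequence is stored column-wise: three n-by-25 matrices (x, y,
# confidence), one column per key-point in BODY_25 order. Confidence 0 marks
# an undetected key-point whose coordinates are meaningless and are never
# read by downstream signal code.

#' BODY_25 key-point names, in network output order
#'
#' Index i of this vector corresponds to key-point i-1 in the usual 0-based
#' BODY_25 numbering (nose = 0, neck = 1, ..., right heel = 24).
#'
#' @export
BODY25_KEYPOINTS <- c(
  "nose", "neck",
  "shoulder_r", "elbow_r", "wrist_r",
  "shoulder_l", "elbow_l", "wrist_l",
  "mid_hip",
  "hip_r", "knee_r", "ankle_r",
  "hip_l", "knee_l", "ankle_l",
  "eye_r", "eye_l", "ear_r", "ear_l",
  "big_toe_l", "small_toe_l", "heel_l",
  "big_toe_r", "small_toe_r", "heel_r"
)

#' Column index of a named BODY_25 key-point
#'
#' @param name key-point name, e.g. `"neck"`, `"ankle_l"`, `"heel_r"`.
#' @return 1-based column index into the key-point matrices.
#' @export
body25_index <- function(name) {
  idx <- match(name, BODY25_KEYPOINTS)
  if (anyNA(idx)) {
    stop("unknown BODY_25 key-point name(s): ",
         paste(name[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Construct a pose sequence
#'
#' @param x,y,conf numeric matrices with one row per frame and 25 columns
#'   (BODY_25 order); `conf` entries lie in \[0, 1\] and a confidence of 0
#'   marks an undetected key-point.
#' @param frame_rate frames per second, > 0.
#' @param video_id opaque identifier.
#' @param frame_index optional integer vector of 0-based frame indices;
#'   defaults to `0:(n-1)`. Must be strictly increasing.
#' @return an object of class `pose_sequence`.
#' @export
pose_sequence <- function(x, y, conf, frame_rate, video_id = "",
                          frame_index = NULL) {
  x <- as.matrix(x); y <- as.matrix(y); conf <- as.matrix(conf)
  n <- nrow(x)
  if (ncol(x) != 25L || ncol(y) != 25L || ncol(conf) != 25L) {
    stop("pose_sequence requires 25 key-point columns")
  }
  if (nrow(y) != n || nrow(conf) != n) {
    stop("x, y and conf must have the same number of frames")
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    stop("frame_rate must be a single positive number")
  }
  if (is.null(frame_index)) frame_index <- seq_len(n) - 1L
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != n || (n > 1L && any(diff(frame_index) <= 0L))) {
    stop("frame_index must be strictly increasing with one entry per frame")
  }
  if (any(conf < 0 | conf > 1, na.rm = TRUE)) {
    stop("confidences must lie in [0, 1]")
  }
  structure(
    list(x = x, y = y, conf = conf,
         frame_rate = as.numeric(frame_rate),
         video_id = as.character(video_id),
         frame_index = frame_index,
         imputed = matrix(FALSE, n, 25L)),
    class = "pose_sequence"
  )
}

#' Number of frames in a pose sequence
#' @param seq a `pose_sequence`.
#' @export
n_frames <- function(seq) nrow(seq$x)

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence> video '%s': %d frames at %g fps (%.1f s)\n",
              x$video_id, n_frames(x), x$frame_rate,
              n_frames(x) / x$frame_rate))
  detected <- mean(x$conf > 0)
  cat(sprintf("  key-points detected on %.1f%% of frame-slots\n",
              100 * detected))
  invisible(x)
}

# Parse one per-frame JSON record; returns a 25x3 matrix (x, y, conf).
# When several people are present, keeps the one whose confidently detected
# key-points span the largest bounding-box area (the patient is the nearest,
# hence largest, person in these recordings).
.parse_openpose_frame <- function(obj, file) {
  people <- obj$people
  if (is.null(people) || length(people) == 0L) {
    return(matrix(0, 25L, 3L))
  }
  best <- NULL
  best_area <- -1
  for (p in people) {
    k <- unlist(p$pose_keypoints_2d, use.names = FALSE)
    if (length(k) != 75L) {
      stop(sprintf("format error in '%s': pose_keypoints_2d has length %d, expected 75",
                   file, length(k)))
    }
    m <- matrix(as.numeric(k), ncol = 3L, byrow = TRUE)
    ok <- m[, 3L] > 0
    area <- if (sum(ok) >= 2L) {
      diff(range(m[ok, 1L])) * diff(range(m[ok, 2L]))
    } else 0
    if (area > best_area) {
      best_area <- area
      best <- m
    }
  }
  best
}

.read_one_json <- function(file) {
  tryCatch(
    jsonlite::fromJSON(file, simplifyVector = FALSE),
    error = function(e) {
      stop(sprintf("malformed JSON in '%s': %s", file, conditionMessage(e)),
           call. = FALSE)
    }
  )
}

#' Read OpenPose BODY_25 key-point frames
#'
#' Accepts either a directory of per-frame `*_keypoints.json` files (read in
#' lexicographic order, the OpenPose convention of zero-padded frame numbers)
#' or a single JSON file containing an array of per-frame records. Each
#' record holds a `people` list whose entries carry a flat
#' `pose_keypoints_2d` array of 75 numbers (x, y, confidence for each of 25
#' key-points). Frames with an empty `people` list become all-zero-confidence
#' frames. When several people are detected the one with the largest
#' confident-key-point bounding box is kept.
#'
#' @param path directory of per-frame files, or a single multi-frame JSON file.
#' @param frame_rate frames per second of the source video.
#' @param video_id identifier stored on the sequence; defaults to the base
#'   name of `path`.
#' @return a [pose_sequence()].
#' @export
read_openpose_frames <- function(path, frame_rate, video_id = NULL) {
  if (is.null(video_id)) video_id <- basename(path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "_keypoints\\.json$",
                             full.names = TRUE))
    if (length(files) == 0L) {
      stop(sprintf("no '*_keypoints.json' files found in '%s'", path))
    }
    frames <- lapply(files, function(f) {
      .parse_openpose_frame(.read_one_json(f), f)
    })
  } else if (file.exists(path)) {
    obj <- .read_one_json(path)
    if (!is.null(obj$people)) obj <- list(obj)  # single-frame file
    frames <- lapply(obj, .parse_openpose_frame, file = path)
  } else {
    stop(sprintf("path '%s' does not exist", path))
  }
  n <- length(frames)
  x <- t(vapply(frames, function(m) m[, 1L], numeric(25L)))
  y <- t(vapply(frames, function(m) m[, 2L], numeric(25L)))
  conf <- t(vapply(frames, function(m) m[, 3L], numeric(25L)))
  conf <- pmin(pmax(conf, 0), 1)
  pose_sequence(x, y, conf, frame_rate = frame_rate, video_id = video_id)
}

#' Write a pose sequence in the OpenPose BODY_25 JSON dialect
#'
#' One `*_keypoints.json` file per frame, named
#' `<video_id>_<frame>_keypoints.json` with a zero-padded frame number so a
#' lexicographic listing restores frame order. Round-trips exactly with
#' [read_openpose_frames()].
#'
#' @param seq a [pose_sequence()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_openpose_frames <- function(seq, dir) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- if (nzchar(seq$video_id)) seq$video_id else "video"
  n <- n_frames(seq)
  paths <- character(n)
  for (i in seq_len(n)) {
    flat <- as.numeric(t(cbind(seq$x[i, ], seq$y[i, ], seq$conf[i, ])))
    rec <- list(version = 1.3,
                people = list(list(person_id = list(-1L),
                                   pose_keypoints_2d = flat)))
    paths[i] <- file.path(dir, sprintf("%s_%012d_keypoints.json",
                                       id, seq$frame_index[i]))
    jsonlite::write_json(rec, paths[i], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Read region-of-interest annotations
#'
#' Expects a delimited text file with header columns `video_id`,
#' `start_frame`, `end_frame`, `direction`, `rating`. Frame intervals are
#' half-open `[start_frame, end_frame)`; `direction` is `"towards"` or
#' `"away"`; `rating` is a clinician severity score in 0-3, or empty when
#' unrated.
#'
#' @param path CSV file path.
#' @return a `data.frame` with one validated row per ROI.
#' @export
read_roi_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("ROI file '%s' does not exist", path))
  d <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("video_id", "start_frame", "end_frame", "direction", "rating")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0L) {
    stop("ROI file is missing column(s): ", paste(missing, collapse = ", "))
  }
  d$video_id <- as.character(d$video_id)
  d$start_frame <- as.integer(d$start_frame)
  d$end_frame <- as.integer(d$end_frame)
  d$direction <- as.character(d$direction)
  if (any(d$end_frame <= d$start_frame)) {
    bad <- which(d$end_frame <= d$start_frame)[1L]
    stop(sprintf("ROI row %d: end_frame (%d) must exceed start_frame (%d)",
                 bad, d$end_frame[bad], d$start_frame[bad]))
  }
  if (!all(d$direction %in% c("towards", "away"))) {
    stop("direction must be 'towards' or 'away'")
  }
  d$rating <- suppressWarnings(as.integer(d$rating))
  has_rating <- !is.na(d$rating)
  if (any(has_rating & !(d$rating %in% 0:3))) {
    stop("rating must be in {0, 1, 2, 3} when present")
  }
  d
}

#' Write ROI annotations
#' @param rois data.frame as returned by [read_roi_annotations()].
#' @param path output CSV path.
#' @export
write_roi_annotations <- function(rois, path) {
  write.csv(rois[, c("video_id", "start_frame", "end_frame",
                     "direction", "rating")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract the frames of one region of interest
#'
#' @param seq a [pose_sequence()].
#' @param roi either a one-row data.frame with `start_frame`/`end_frame`
#'   columns, or a list with those fields. The interval is half-open.
#' @return a [pose_sequence()] restricted to frames `[start, end)`; the frame
#'   rate is preserved and frame indices keep their original values.
#' @export
slice_roi <- function(seq, roi) {
  stopifnot(inherits(seq, "pose_sequence"))
  start <- as.integer(roi$start_frame)
  end <- as.integer(roi$end_frame)
  if (end <= start) stop("ROI end_frame must exceed start_frame")
  fi <- seq$frame_index
  if (start < fi[1L] || end > fi[length(fi)] + 1L) {
    stop(sprintf("ROI [%d, %d) is out of bounds for frames [%d, %d]",
                 start, end, fi[1L], fi[length(fi)]))
  }
  keep <- fi >= start & fi < end
  out <- seq
  out$x <- seq$x[keep, , drop = FALSE]
  out$y <- seq$y[keep, , drop = FALSE]
  out$conf <- seq$conf[keep, , drop = FALSE]
  out$imputed <- seq$imputed[keep, , drop = FALSE]
  out$frame_index <- fi[keep]
  out
}

#' Interpolate short key-point dropouts
#'
#' Pose networks intermittently fail to detect individual key-points
#' (confidence 0). For each key-point, zero-confidence runs no longer than
#' `max_gap` seconds that are bounded on both sides by confident frames are
#' filled by linear interpolation of x and y; the filled slots receive the
#' smaller of the two bounding confidences and are flagged in the sequence's
#' `imputed` matrix. Longer runs, and runs touching either end of the
#' sequence, are left missing. The default gap of 0.5 s is shorter than half
#' a slow gait cycle, so interpolation cannot invent step events.
#'
#' The operation is idempotent.
#'
#' @param seq a [pose_sequence()].
#' @param max_gap longest gap to fill, in seconds.
#' @return the gap-filled [pose_sequence()].
#' @export
fill_missing_keypoints <- function(seq, max_gap = 0.5) {
  stopifnot(inherits(seq, "pose_sequence"))
  n <- n_frames(seq)
  max_run <- floor(max_gap * seq$frame_rate + 1e-9)
  if (max_run < 1L || n < 3L) return(seq)
  for (j in seq_len(25L)) {
    miss <- seq$conf[, j] <= 0
    if (!any(miss) || all(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$lengths)) {
      if (!r$values[k] || r$lengths[k] > max_run) next
      a <- starts[k] - 1L
      b <- ends[k] + 1L
      if (a < 1L || b > n) next  # gap touches the boundary
      idx <- starts[k]:ends[k]
      w <- (idx - a) / (b - a)
      seq$x[idx, j] <- seq$x[a, j] + w * (seq$x[b, j] - seq$x[a, j])
      seq$y[idx, j] <- seq$y[a, j] + w * (seq$y[b, j] - seq$y[a, j])
      seq$conf[idx, j] <- min(seq$conf[a, j], seq$conf[b, j])
      seq$imputed[idx, j] <- TRUE
    }
  }
  seq
}
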