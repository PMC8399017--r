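# The seven normalised gait time-series signals and gait-cycle event
# detection.
#
# Signals are plain numeric vectors on the ROI's frame axis, with NA marking
# frames where a required key-point is undetected (the validity mask).

.dist2d <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)

.kp_valid <- function(seq, name) seq$conf[, body25_index(name)] > 0
.kp_x <- function(seq, name) seq$x[, body25_index(name)]
.kp_y <- function(seq, name) seq$y[, body25_index(name)]

#' Estimate the patient's standing height in pixels
#'
#' Per frame, height is taken as 1.25 times the Euclidean distance from the
#' neck key-point to the midpoint of the two ankles (when only one ankle is
#' detected, that ankle stands in for the midpoint). The factor reflects
#' that the neck-to-ankle span covers roughly 80% of standing height. The
#' ROI-level height is the median over valid frames, which resists
#' occasional pose jitter and detection outliers.
#'
#' @param seq a [pose_sequence()].
#' @return an object of class `height_estimate` with fields `per_frame`
#'   (numeric, NA where undefined) and `height` (the ROI-level median).
#' @export
estimate_height <- function(seq) {
  stopifnot(inherits(seq, "pose_sequence"))
  neck_ok <- .kp_valid(seq, "neck")
  al_ok <- .kp_valid(seq, "ankle_l")
  ar_ok <- .kp_valid(seq, "ankle_r")
  ax <- ifelse(al_ok & ar_ok, (.kp_x(seq, "ankle_l") + .kp_x(seq, "ankle_r")) / 2,
        ifelse(al_ok, .kp_x(seq, "ankle_l"),
        ifelse(ar_ok, .kp_x(seq, "ankle_r"), NA_real_)))
  ay <- ifelse(al_ok & ar_ok, (.kp_y(seq, "ankle_l") + .kp_y(seq, "ankle_r")) / 2,
        ifelse(al_ok, .kp_y(seq, "ankle_l"),
        ifelse(ar_ok, .kp_y(seq, "ankle_r"), NA_real_)))
  per_frame <- ifelse(neck_ok & !is.na(ax),
                      1.25 * .dist2d(.kp_x(seq, "neck"), .kp_y(seq, "neck"), ax, ay),
                      NA_real_)
  per_frame[!is.na(per_frame) & per_frame <= 0] <- NA_real_
  if (all(is.na(per_frame))) {
    stop("height estimation failed: no frame has a confident neck and ankle")
  }
  structure(list(per_frame = per_frame,
                 height = median(per_frame, na.rm = TRUE)),
            class = "height_estimate")
}

# atan of dy/dx with the vertical-baseline limit: dx == 0 gives +/- pi/2.
.atan_slope <- function(dy, dx) {
  out <- atan(dy / dx)
  vert <- !is.na(dx) & dx == 0
  out[vert] <- sign(dy[vert]) * pi / 2
  out
}

#' Compute the seven normalised gait signals
#'
#' All signals share the ROI's frame axis; frames lacking a required
#' key-point are NA. Key-point naming follows BODY_25 (left/right from the
#' patient's perspective; image origin top-left, y downwards).
#'
#' * `r_legs` — apparent left/right leg-length ratio difference
#'   `|hipL-ankleL|/|hipR-ankleR| - |hipR-ankleR|/|hipL-ankleL|`;
#'   oscillates once per stride as the legs pass each other.
#' * `a_body_vert` — angle (rad) between the image y-axis and the
#'   neck-to-ankle-midpoint line: `asin((x_neck - x_anklemid)/d)`.
#' * `a_ankles_horiz`, `a_wrists_horiz` — angle (rad) between the image
#'   x-axis and the left-right ankle (wrist) line, `atan(dy/dx)`.
#' * `d_heels_horiz` — `|x_heelL - x_heelR| / H(t)`, height-normalised.
#' * `d_ankle_l`, `d_ankle_r` — height-normalised Euclidean displacement of
#'   each ankle between successive frames (length n-1).
#'
#' @param seq a [pose_sequence()] restricted to one ROI.
#' @param height optional [estimate_height()] result; computed if missing.
#' @return an object of class `signal_set`.
#' @export
compute_signal_set <- function(seq, height = NULL) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (is.null(height)) height <- estimate_height(seq)
  n <- n_frames(seq)
  H <- height$per_frame
  H[is.na(H)] <- height$height

  # leg ratio difference
  lok <- .kp_valid(seq, "hip_l") & .kp_valid(seq, "ankle_l")
  rok <- .kp_valid(seq, "hip_r") & .kp_valid(seq, "ankle_r")
  lleg <- .dist2d(.kp_x(seq, "hip_l"), .kp_y(seq, "hip_l"),
                  .kp_x(seq, "ankle_l"), .kp_y(seq, "ankle_l"))
  rleg <- .dist2d(.kp_x(seq, "hip_r"), .kp_y(seq, "hip_r"),
                  .kp_x(seq, "ankle_r"), .kp_y(seq, "ankle_r"))
  ok <- lok & rok & lleg > 0 & rleg > 0
  r_legs <- ifelse(ok, lleg / rleg - rleg / lleg, NA_real_)

  # vertical body angle
  aok <- .kp_valid(seq, "ankle_l") & .kp_valid(seq, "ankle_r") &
    .kp_valid(seq, "neck")
  amx <- (.kp_x(seq, "ankle_l") + .kp_x(seq, "ankle_r")) / 2
  amy <- (.kp_y(seq, "ankle_l") + .kp_y(seq, "ankle_r")) / 2
  d_na <- .dist2d(.kp_x(seq, "neck"), .kp_y(seq, "neck"), amx, amy)
  arg <- (.kp_x(seq, "neck") - amx) / d_na
  arg <- pmin(pmax(arg, -1), 1)  # guard asin against fp overshoot
  a_body_vert <- ifelse(aok & d_na > 0, asin(arg), NA_real_)

  # horizontal ankle / wrist angles (left minus right)
  kok <- .kp_valid(seq, "ankle_l") & .kp_valid(seq, "ankle_r")
  a_ankles_horiz <- ifelse(
    kok,
    .atan_slope(.kp_y(seq, "ankle_l") - .kp_y(seq, "ankle_r"),
                .kp_x(seq, "ankle_l") - .kp_x(seq, "ankle_r")),
    NA_real_)
  wok <- .kp_valid(seq, "wrist_l") & .kp_valid(seq, "wrist_r")
  a_wrists_horiz <- ifelse(
    wok,
    .atan_slope(.kp_y(seq, "wrist_l") - .kp_y(seq, "wrist_r"),
                .kp_x(seq, "wrist_l") - .kp_x(seq, "wrist_r")),
    NA_real_)

  # heel separation, height-normalised
  hok <- .kp_valid(seq, "heel_l") & .kp_valid(seq, "heel_r")
  d_heels_horiz <- ifelse(
    hok,
    abs(.kp_x(seq, "heel_l") - .kp_x(seq, "heel_r")) / H,
    NA_real_)

  # per-ankle frame-to-frame speed (length n - 1)
  ankle_speed <- function(name, ok) {
    xx <- .kp_x(seq, name); yy <- .kp_y(seq, name)
    step <- .dist2d(xx[-n], yy[-n], xx[-1L], yy[-1L]) / H[-n]
    ifelse(ok[-n] & ok[-1L], step, NA_real_)
  }
  d_ankle_l <- ankle_speed("ankle_l", .kp_valid(seq, "ankle_l"))
  d_ankle_r <- ankle_speed("ankle_r", .kp_valid(seq, "ankle_r"))

  structure(
    list(r_legs = r_legs,
         a_body_vert = a_body_vert,
         a_ankles_horiz = a_ankles_horiz,
         a_wrists_horiz = a_wrists_horiz,
         d_heels_horiz = d_heels_horiz,
         d_ankle_l = d_ankle_l,
         d_ankle_r = d_ankle_r,
         frame_rate = seq$frame_rate,
         n_frames = n,
         video_id = seq$video_id),
    class = "signal_set"
  )
}

# Centred moving average with shrinking windows at the edges (no NA padding).
.moving_average <- function(z, w) {
  n <- length(z)
  if (w <= 1L || n == 0L) return(z)
  lo <- pmax(seq_len(n) - (w - 1L) %/% 2L, 1L)
  hi <- pmin(seq_len(n) + w %/% 2L, n)
  cs <- cumsum(c(0, z))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Strict local maxima of z (plateaus yield one index at the plateau's end).
.local_maxima <- function(z) {
  n <- length(z)
  if (n < 3L) return(integer())
  s <- sign(diff(z))
  for (i in seq_along(s)) {
    if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  }
  which(diff(s) < 0) + 1L
}

# Topographic prominence of the peak at index i of z.
.peak_prominence <- function(z, i) {
  h <- z[i]
  side_min <- function(idx_seq) {
    m <- h
    for (j in idx_seq) {
      if (z[j] > h) break
      if (z[j] < m) m <- z[j]
    }
    m
  }
  left <- if (i > 1L) side_min((i - 1L):1L) else h
  right <- if (i < length(z)) side_min((i + 1L):length(z)) else h
  h - max(left, right)
}

# Peaks of z with prominence >= min_prom, at least min_dist frames apart
# (higher-prominence peaks win). Returns a data.frame(index, prominence).
.find_peaks <- function(z, min_prom, min_dist) {
  cand <- .local_maxima(z)
  if (length(cand) == 0L) {
    return(data.frame(index = integer(), prominence = numeric()))
  }
  prom <- vapply(cand, function(i) .peak_prominence(z, i), numeric(1))
  keep <- prom >= min_prom & prom > 0
  cand <- cand[keep]; prom <- prom[keep]
  ord <- order(prom, decreasing = TRUE)
  sel <- integer()
  for (i in ord) {
    if (all(abs(cand[sel] - cand[i]) >= min_dist)) sel <- c(sel, i)
  }
  sel <- sel[order(cand[sel])]
  data.frame(index = cand[sel], prominence = prom[sel])
}

#' Detect peak and trough events in one gait signal
#'
#' The series is centred, smoothed with a moving average of
#' `round(frame_rate / 6)` frames, and local maxima are retained as peaks
#' when their topographic prominence reaches `prominence_factor` times the
#' scaled median absolute deviation (1.4826 x MAD) of the smoothed series,
#' with an inter-peak separation of at least `min_separation` seconds
#' (0.2 s sits just above the half-period of the fastest plausible cadence).
#' Troughs are peaks of the negated series under the same rules. Alternation
#' is enforced by discarding the lower-prominence member of any same-type
#' adjacent pair. Missing (NA) frames are bridged by linear interpolation
#' for smoothing only; events are never placed on missing frames.
#'
#' @param series numeric vector, NA on invalid frames.
#' @param frame_rate frames per second.
#' @param prominence_factor multiple of the scaled MAD required; default 0.5.
#' @param min_separation minimum event separation in seconds; default 0.2.
#' @param smooth_window moving-average width in frames; default
#'   `round(frame_rate / 6)`.
#' @return list with integer vectors `peaks` and `troughs` (1-based frame
#'   positions within the series, strictly alternating).
#' @export
detect_events <- function(series, frame_rate,
                          prominence_factor = 0.5,
                          min_separation = 0.2,
                          smooth_window = NULL) {
  valid <- is.finite(series)
  empty <- list(peaks = integer(), troughs = integer())
  if (sum(valid) < 3L) return(empty)
  n <- length(series)
  idx <- seq_len(n)
  z <- series
  if (!all(valid)) {
    z <- approx(idx[valid], series[valid], xout = idx, rule = 2)$y
  }
  z <- z - mean(z)
  if (is.null(smooth_window)) smooth_window <- max(1L, round(frame_rate / 6))
  zs <- .moving_average(z, smooth_window)
  thr <- prominence_factor * mad(zs)
  min_dist <- max(1L, ceiling(min_separation * frame_rate))
  pk <- .find_peaks(zs, thr, min_dist)
  tr <- .find_peaks(-zs, thr, min_dist)
  ev <- rbind(
    if (nrow(pk)) cbind(pk, type = 1) else NULL,
    if (nrow(tr)) cbind(tr, type = -1) else NULL
  )
  if (is.null(ev) || nrow(ev) == 0L) return(empty)
  ev <- ev[valid[ev$index], , drop = FALSE]  # never on masked frames
  ev <- ev[order(ev$index), , drop = FALSE]
  # enforce strict peak/trough alternation
  while (nrow(ev) >= 2L) {
    same <- which(diff(ev$type) == 0)
    if (length(same) == 0L) break
    i <- same[1L]
    drop <- if (ev$prominence[i] < ev$prominence[i + 1L]) i else i + 1L
    ev <- ev[-drop, , drop = FALSE]
  }
  list(peaks = ev$index[ev$type == 1], troughs = ev$index[ev$type == -1])
}

#' Detect events on the four event-bearing signals
#'
#' Applies [detect_events()] to `r_legs`, `a_body_vert`, `a_ankles_horiz`
#' and `a_wrists_horiz`. Peaks and troughs of these signals mark the ends of
#' gait (half-)cycles: the leg-ratio signal, for instance, is extremal when
#' the legs are maximally split.
#'
#' @param signals a [compute_signal_set()] result.
#' @param ... passed on to [detect_events()].
#' @return named list of `list(peaks, troughs)` entries.
#' @export
detect_all_events <- function(signals, ...) {
  stopifnot(inherits(signals, "signal_set"))
  nm <- c("r_legs", "a_body_vert", "a_ankles_horiz", "a_wrists_horiz")
  setNames(lapply(nm, function(s) {
    detect_events(signals[[s]], signals$frame_rate, ...)
  }), nm)
}

#' Long-format export of a signal set
#'
#' @param signals a [compute_signal_set()] result.
#' @param video_id,roi_id identifiers stamped on every row.
#' @return data.frame with columns video_id, roi, signal_name, frame, value,
#'   valid.
#' @export
signals_to_long <- function(signals, video_id = signals$video_id, roi_id = 1L) {
  stopifnot(inherits(signals, "signal_set"))
  nm <- c("r_legs", "a_body_vert", "a_ankles_horiz", "a_wrists_horiz",
          "d_heels_horiz", "d_ankle_l", "d_ankle_r")
  do.call(rbind, lapply(nm, function(s) {
    v <- signals[[s]]
    data.frame(video_id = video_id, roi = roi_id, signal_name = s,
               frame = seq_along(v) - 1L, value = v, valid = is.finite(v))
  }))
}
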