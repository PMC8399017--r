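# The six clinically interpretable gait features.
#
# All features are unit-free or angle-based and therefore invariant to
# uniform scaling and translation of the image coordinates (signals are
# height-normalised or angles). The two ankle-roughness values are re-coded
# as (min, max) so the feature vector does not depend on laterality.

.feature_error <- function(name, why) {
  stop(sprintf("feature '%s' undefined: %s", name, why), call. = FALSE)
}

#' Arm swing velocity
#'
#' Median absolute first difference of the wrist-angle signal, in radians
#' per frame. Only consecutive frame pairs where both values are defined
#' contribute.
#'
#' @param series the `a_wrists_horiz` signal (radians, NA on masked frames).
#' @return median |x(t+1) - x(t)| over valid pairs.
#' @export
arm_swing_velocity <- function(series) {
  d <- abs(diff(series))
  d <- d[is.finite(d)]
  if (length(d) < 1L) {
    .feature_error("arm_swing_velocity", "fewer than 2 consecutive valid frames")
  }
  median(d)
}

#' Arm swing amplitude
#'
#' The detected troughs span a piecewise-linear "lower bound" under the
#' wrist-angle signal (extended flat beyond the outermost troughs); the
#' height of the signal above this bound is measured at each detected peak
#' and the per-peak heights are summarised. For a clean oscillation this
#' recovers the peak-to-trough amplitude while absorbing slow drift into
#' the bound.
#'
#' @param series the `a_wrists_horiz` signal (radians).
#' @param events `list(peaks, troughs)` for that signal from
#'   [detect_events()]; at least 1 peak and 2 troughs are required.
#' @param summary `"mean"` (default) or `"median"` over per-peak heights.
#' @return amplitude in radians.
#' @export
arm_swing_amplitude <- function(series, events, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  peaks <- events$peaks
  troughs <- events$troughs
  if (length(peaks) < 1L || length(troughs) < 2L) {
    .feature_error("arm_swing_amplitude",
                   sprintf("needs >= 1 peak and >= 2 troughs (got %d, %d)",
                           length(peaks), length(troughs)))
  }
  lower <- approx(troughs, series[troughs], xout = peaks, rule = 2)$y
  heights <- series[peaks] - lower
  heights <- heights[is.finite(heights)]
  if (length(heights) == 0L) {
    .feature_error("arm_swing_amplitude", "no finite per-peak heights")
  }
  if (summary == "mean") mean(heights) else median(heights)
}

#' Roughness of ankle movement
#'
#' Per frame, the absolute change in normalised ankle speed divided by the
#' speed itself, `|speed(t+1) - speed(t)| / speed(t)`, summarised by the
#' median. Frames with speed below `eps` are excluded so that near-stationary
#' ankles do not produce unbounded ratios. Smooth movement yields values near
#' zero; jerky movement yields large values.
#'
#' @param speed_series one of the `d_ankle_*` signals (height-normalised
#'   displacement per frame).
#' @param eps division guard on the normalised speed; default 1e-6.
#' @return median relative speed change (unitless).
#' @export
roughness <- function(speed_series, eps = 1e-6) {
  s <- speed_series
  n <- length(s)
  if (n < 3L) .feature_error("roughness", "fewer than 3 frames")
  num <- abs(s[-1L] - s[-n])
  den <- s[-n]
  r <- num / den
  r <- r[is.finite(r) & den > eps]
  if (length(r) == 0L) .feature_error("roughness", "no valid ratio frames")
  median(r)
}

#' Postural control (stride-width variability)
#'
#' Coefficient of variation of the heel-separation signal over its valid
#' frames, using the population standard deviation for determinism. Lower
#' values indicate less stride-width variability; reduced variability is
#' characteristic of Parkinsonian gait.
#'
#' @param series the `d_heels_horiz` signal.
#' @return SD / mean (unitless).
#' @export
postural_control <- function(series) {
  v <- series[is.finite(series)]
  if (length(v) < 2L) {
    .feature_error("postural_control", "fewer than 2 valid frames")
  }
  m <- mean(v)
  if (m <= 0) .feature_error("postural_control", "non-positive mean")
  sd_pop <- sqrt(mean((v - m)^2))
  sd_pop / m
}

#' Names and order of the gait feature vector
#' @export
GAIT_FEATURES <- c("speed", "arm_swing_velocity", "arm_swing_amplitude",
                   "postural_control", "roughness_min", "roughness_max")

#' Assemble the six-feature gait vector
#'
#' Combines the cadence point estimate with the five signal-derived
#' features, re-coding left/right ankle roughness as (min, max).
#'
#' @param signals a [compute_signal_set()] result.
#' @param events named event list from [detect_all_events()] (the
#'   `a_wrists_horiz` entry is used for arm swing amplitude).
#' @param freq step-frequency point estimate in Hz, or a
#'   [estimate_step_frequency()] result.
#' @return named numeric vector in the order of [GAIT_FEATURES].
#' @export
extract_features <- function(signals, events, freq) {
  stopifnot(inherits(signals, "signal_set"))
  if (inherits(freq, "step_frequency_estimate")) freq <- freq$point
  if (!is.finite(freq) || freq <= 0) {
    .feature_error("speed", "step-frequency estimate must be positive")
  }
  rough_l <- roughness(signals$d_ankle_l)
  rough_r <- roughness(signals$d_ankle_r)
  out <- c(
    speed = freq,
    arm_swing_velocity = arm_swing_velocity(signals$a_wrists_horiz),
    arm_swing_amplitude = arm_swing_amplitude(signals$a_wrists_horiz,
                                              events$a_wrists_horiz),
    postural_control = postural_control(signals$d_heels_horiz),
    roughness_min = min(rough_l, rough_r),
    roughness_max = max(rough_l, rough_r)
  )
  out[GAIT_FEATURES]
}

#' Run the full per-ROI pipeline: signals, events, cadence, features
#'
#' Convenience wrapper applying gap filling, height estimation, signal
#' construction, event detection, the Gamma-Poisson cadence model, and
#' feature assembly to a single pose sequence (typically one ROI).
#'
#' @param seq a [pose_sequence()].
#' @param fill_gaps interpolate short key-point dropouts first; default TRUE.
#' @param max_gap see [fill_missing_keypoints()].
#' @param prior cadence prior; default [init_prior()].
#' @param ... passed to [detect_events()].
#' @return list with `features` (named numeric), `step_frequency`
#'   (full estimate object), `signals`, `events`, `height`.
#' @export
extract_gait_features <- function(seq, fill_gaps = TRUE, max_gap = 0.5,
                                  prior = init_prior(), ...) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (fill_gaps) seq <- fill_missing_keypoints(seq, max_gap = max_gap)
  height <- estimate_height(seq)
  signals <- compute_signal_set(seq, height)
  events <- detect_all_events(signals, ...)
  stream <- build_event_stream(events[c("r_legs", "a_body_vert", "a_ankles_horiz")],
                               n_frames = signals$n_frames,
                               frame_rate = signals$frame_rate)
  sf <- estimate_step_frequency(stream, prior = prior)
  feats <- extract_features(signals, events, sf)
  list(features = feats, step_frequency = sf, signals = signals,
       events = events, height = height)
}
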