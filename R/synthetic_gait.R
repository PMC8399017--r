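# Synthetic BODY_25 walking sequences with known ground truth.
#
# The generator produces sinusoidal skeleton kinematics rather than a
# biomechanical simulation: the downstream pipeline consumes only the
# oscillatory structure, amplitudes and noise levels that the gait signals
# measure, all of which are controlled here. One stride (a full left+right
# gait cycle) spans two steps, so the leg-driven signals oscillate at half
# the step frequency and contribute one peak plus one trough per stride --
# i.e. a per-signal event rate equal to the step frequency, the quantity
# the Gamma-Poisson cadence model estimates.

#' Parameters of a simulated walk
#'
#' @param step_frequency steps per second (Hz), inside the plausible
#'   (0.24, 5.57) Hz cadence range.
#' @param arm_swing_amplitude_factor scales wrist oscillation; 0 = no arm
#'   swing, 1 = full swing.
#' @param stride_width_cv coefficient of variation of the heel separation
#'   (drives the postural-control feature).
#' @param jerk_noise standard deviation (pixels) of white noise added to the
#'   ankle and heel trajectories (drives the roughness features).
#' @param stoop forward-lean angle in radians (offsets the vertical body
#'   angle).
#' @param direction `"towards"` (apparent size grows) or `"away"` (shrinks).
#' @param duration seconds of walking; `duration * frame_rate >= 60` frames.
#' @param frame_rate frames per second; default 30.
#' @param keypoint_jitter_sd Gaussian key-point jitter in pixels.
#' @param dropout_rate probability that a key-point detection is dropped
#'   (confidence 0) on a frame.
#' @param seed RNG seed; the same seed reproduces the walk bit for bit.
#' @return an object of class `gait_sim_params`.
#' @export
gait_sim_params <- function(step_frequency = 2,
                            arm_swing_amplitude_factor = 1,
                            stride_width_cv = 0.25,
                            jerk_noise = 1,
                            stoop = 0,
                            direction = c("towards", "away"),
                            duration = 7,
                            frame_rate = 30,
                            keypoint_jitter_sd = 1,
                            dropout_rate = 0.02,
                            seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(step_frequency > 0.24, step_frequency < 5.57,
            arm_swing_amplitude_factor >= 0, arm_swing_amplitude_factor <= 1,
            stride_width_cv >= 0, jerk_noise >= 0,
            duration * frame_rate >= 60,
            frame_rate > 0, keypoint_jitter_sd >= 0,
            dropout_rate >= 0, dropout_rate <= 1)
  structure(list(step_frequency = step_frequency,
                 arm_swing_amplitude_factor = arm_swing_amplitude_factor,
                 stride_width_cv = stride_width_cv,
                 jerk_noise = jerk_noise,
                 stoop = stoop,
                 direction = direction,
                 duration = duration,
                 frame_rate = frame_rate,
                 keypoint_jitter_sd = keypoint_jitter_sd,
                 dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "gait_sim_params")
}

# smooth unit-variance noise: white noise passed through a half-second
# moving average, re-standardised
.smooth_noise <- function(n, frame_rate) {
  z <- .moving_average(rnorm(n), max(3L, round(frame_rate / 2)))
  s <- sd(z)
  if (!is.finite(s) || s == 0) return(rep(0, n))
  (z - mean(z)) / s
}

#' Simulate one walking sequence
#'
#' @param params a [gait_sim_params()].
#' @return list with `sequence` (a [pose_sequence()]) and `truth` (realised
#'   step frequency, per-signal event times/frames, and feature-level
#'   targets such as the wrist-angle amplitude).
#' @export
simulate_walk <- function(params) {
  stopifnot(inherits(params, "gait_sim_params"))
  set.seed(params$seed)
  fr <- params$frame_rate
  n <- round(params$duration * fr)
  t <- (seq_len(n) - 1L) / fr
  f <- params$step_frequency
  phase <- runif(1, 0, 2 * pi)
  psi <- 2 * pi * (f / 2) * t + phase  # stride phase

  # unscaled skeleton offsets (pixels at unit scale), y grows downwards
  dx <- matrix(0, n, 25L)
  dy <- matrix(0, n, 25L)
  set_kp <- function(name, xs, ys) {
    j <- body25_index(name)
    dx[, j] <<- xs
    dy[, j] <<- ys
  }
  sway <- 8 * sin(psi)
  stoop_dx <- 170 * sin(params$stoop)
  set_kp("neck", stoop_dx + sway, -170)
  set_kp("nose", stoop_dx + sway, -196)
  set_kp("eye_r", stoop_dx + sway - 6, -200)
  set_kp("eye_l", stoop_dx + sway + 6, -200)
  set_kp("ear_r", stoop_dx + sway - 12, -196)
  set_kp("ear_l", stoop_dx + sway + 12, -196)
  set_kp("shoulder_r", stoop_dx + sway - 28, -160)
  set_kp("shoulder_l", stoop_dx + sway + 28, -160)
  set_kp("elbow_r", -55, -95)
  set_kp("elbow_l", 55, -95)
  arm <- 22 * params$arm_swing_amplitude_factor * sin(psi + pi)
  set_kp("wrist_r", -70, -40 - arm)
  set_kp("wrist_l", 70, -40 + arm)
  set_kp("mid_hip", 0, 0)
  set_kp("hip_r", -22, 0)
  set_kp("hip_l", 22, 0)
  set_kp("knee_r", -24, 85)
  set_kp("knee_l", 24, 85)
  # legs: left/right antiphase length oscillation (apparent shortening of
  # the swinging leg) plus a common fore-aft sway of both feet in the image
  # plane, sized so the per-frame ankle displacement dominates key-point
  # jitter at realistic noise levels
  leg_a <- 0.14
  swing <- 45 * sin(psi)
  al_y <- 175 * (1 + leg_a * sin(psi))
  ar_y <- 175 * (1 - leg_a * sin(psi))
  set_kp("ankle_l", 26 + swing, al_y)
  set_kp("ankle_r", -26 + swing, ar_y)
  sep <- 44 * pmax(1 + params$stride_width_cv * .smooth_noise(n, fr), 0.15)
  set_kp("heel_l", swing + sep / 2, al_y + 6)
  set_kp("heel_r", swing - sep / 2, ar_y + 6)
  set_kp("big_toe_l", swing + sep / 2 + 14, al_y + 8)
  set_kp("small_toe_l", swing + sep / 2 + 18, al_y + 7)
  set_kp("big_toe_r", swing - sep / 2 - 14, ar_y + 8)
  set_kp("small_toe_r", swing - sep / 2 - 18, ar_y + 7)

  # jerk noise on the ankle trajectories (drives roughness)
  if (params$jerk_noise > 0) {
    for (name in c("ankle_l", "ankle_r")) {
      j <- body25_index(name)
      dx[, j] <- dx[, j] + rnorm(n, 0, params$jerk_noise)
      dy[, j] <- dy[, j] + rnorm(n, 0, params$jerk_noise)
    }
  }

  # apparent-size change as the patient approaches or recedes
  sc <- seq(0.75, 1.25, length.out = n)
  if (params$direction == "away") sc <- rev(sc)
  x <- 640 + dx * sc
  y <- 360 + (dy - 85) * sc

  # observation noise and detection dropout
  if (params$keypoint_jitter_sd > 0) {
    x <- x + matrix(rnorm(n * 25L, 0, params$keypoint_jitter_sd), n, 25L)
    y <- y + matrix(rnorm(n * 25L, 0, params$keypoint_jitter_sd), n, 25L)
  }
  conf <- matrix(runif(n * 25L, 0.55, 0.95), n, 25L)
  if (params$dropout_rate > 0) {
    conf[matrix(runif(n * 25L) < params$dropout_rate, n, 25L)] <- 0
  }

  sequence <- pose_sequence(x, y, conf, frame_rate = fr,
                            video_id = sprintf("sim_seed%d", params$seed))

  # step events occur at the extrema of sin(psi): psi = pi/2 + m * pi
  m_range <- ceiling((psi[1L] - pi / 2) / pi):floor((psi[n] - pi / 2) / pi)
  event_times <- ((pi / 2 + m_range * pi) - phase) / (2 * pi * (f / 2))
  event_times <- event_times[event_times >= 0 & event_times <= t[n]]
  truth <- list(
    step_frequency = f,
    stride_frequency = f / 2,
    event_times = event_times,
    event_frames = unique(round(event_times * fr)),
    n_strides = params$duration * f / 2,
    arm_angle_amplitude = 2 * atan(2 * 22 * params$arm_swing_amplitude_factor / 140),
    stride_width_cv = params$stride_width_cv,
    params = params
  )
  list(sequence = sequence, truth = truth)
}

#' Default severity-to-parameter map for cohort simulation
#'
#' Severity 0 (normal) through 3 (moderate impairment) are emulated by
#' slowing cadence, attenuating arm swing, reducing stride-width
#' variability and increasing movement jerk -- the qualitative directions
#' in which these gait characteristics change with worsening Parkinsonian
#' gait. Each entry gives the mean and between-patient SD of the four
#' severity-linked generator parameters.
#'
#' @return list of four per-severity parameter distributions.
#' @export
default_severity_map <- function() {
  list(
    `0` = list(step_frequency = c(2.10, 0.15),
               arm_swing_amplitude_factor = c(0.95, 0.10),
               jerk_noise = c(0.8, 0.3),
               stride_width_cv = c(0.30, 0.03)),
    `1` = list(step_frequency = c(1.85, 0.15),
               arm_swing_amplitude_factor = c(0.65, 0.10),
               jerk_noise = c(1.4, 0.3),
               stride_width_cv = c(0.24, 0.03)),
    `2` = list(step_frequency = c(1.60, 0.15),
               arm_swing_amplitude_factor = c(0.40, 0.10),
               jerk_noise = c(2.2, 0.3),
               stride_width_cv = c(0.18, 0.03)),
    `3` = list(step_frequency = c(1.35, 0.15),
               arm_swing_amplitude_factor = c(0.20, 0.08),
               jerk_noise = c(3.0, 0.3),
               stride_width_cv = c(0.13, 0.03))
  )
}

.draw_truncnorm <- function(mean_sd, lo, hi) {
  min(max(rnorm(1, mean_sd[1], mean_sd[2]), lo), hi)
}

#' Simulate a rated cohort and extract its feature table
#'
#' Each video receives a severity rating (imbalanced by default, low scores
#' more common as in routine clinical data), severity-linked walk
#' parameters, and two ROIs -- one walking towards and one away from the
#' camera -- sharing the video id, label and gait parameters. The full
#' pipeline ([extract_gait_features()]) is run on every ROI.
#'
#' @param n_videos number of videos; default 400.
#' @param class_probs sampling probabilities of severities 0-3.
#' @param severity_map per-severity parameter distributions; default
#'   [default_severity_map()].
#' @param duration,frame_rate per-ROI length; defaults 7 s at 30 fps.
#' @param keypoint_jitter_sd,dropout_rate observation noise; defaults 1 px
#'   and 2%.
#' @param seed master seed; the whole cohort is reproducible from it.
#' @return data.frame with one row per ROI: `video_id`, `roi_id`,
#'   `direction`, `rating`, the six [GAIT_FEATURES] columns, and
#'   `truth_step_frequency`. ROIs whose features are undefined (e.g. no
#'   detectable events) are dropped; their count is in attribute
#'   `n_failed`.
#' @export
simulate_cohort <- function(n_videos = 400L,
                            class_probs = c(0.25, 0.40, 0.25, 0.10),
                            severity_map = default_severity_map(),
                            duration = 7, frame_rate = 30,
                            keypoint_jitter_sd = 1, dropout_rate = 0.02,
                            seed = 1L) {
  set.seed(seed)
  ratings <- sample(0:3, n_videos, replace = TRUE, prob = class_probs)
  walk_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n_videos),
                       n_videos, 2L)
  rows <- vector("list", 2L * n_videos)
  n_failed <- 0L
  for (v in seq_len(n_videos)) {
    set.seed(walk_seeds[v, 1L])
    m <- severity_map[[as.character(ratings[v])]]
    sf <- .draw_truncnorm(m$step_frequency, 0.5, 4.0)
    af <- .draw_truncnorm(m$arm_swing_amplitude_factor, 0.02, 1.0)
    jn <- max(rnorm(1, m$jerk_noise[1], m$jerk_noise[2]), 0.05)
    cv <- .draw_truncnorm(m$stride_width_cv, 0.02, 0.50)
    for (d in 1:2) {
      direction <- c("towards", "away")[d]
      params <- gait_sim_params(
        step_frequency = sf,
        arm_swing_amplitude_factor = af,
        stride_width_cv = cv,
        jerk_noise = jn,
        direction = direction,
        duration = duration,
        frame_rate = frame_rate,
        keypoint_jitter_sd = keypoint_jitter_sd,
        dropout_rate = dropout_rate,
        seed = walk_seeds[v, d])
      walk <- simulate_walk(params)
      feats <- tryCatch(extract_gait_features(walk$sequence)$features,
                        error = function(e) NULL)
      if (is.null(feats)) {
        n_failed <- n_failed + 1L
        next
      }
      rows[[2L * (v - 1L) + d]] <- data.frame(
        video_id = sprintf("video_%04d", v),
        roi_id = d,
        direction = direction,
        rating = ratings[v],
        as.data.frame(as.list(feats)),
        truth_step_frequency = sf)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "n_failed") <- n_failed
  out
}
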