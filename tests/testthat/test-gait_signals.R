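# Construction of the seven normalised gait signals and event detection.

test_that("height is 1.25 x neck-to-ankle-midpoint distance, median-pooled", {
  seq <- toy_pose_seq(n = 3, kp = list(
    neck = c(100, 100), ankle_l = c(90, 500), ankle_r = c(110, 500)))
  h <- estimate_height(seq)
  expect_equal(h$per_frame, rep(500, 3))  # 1.25 * sqrt(0^2 + 400^2)
  expect_equal(h$height, 500)             # median of constants

  # one outlier frame among many identical frames leaves the median unchanged
  seq2 <- toy_pose_seq(n = 100, kp = list(
    neck = c(100, 100), ankle_l = c(90, 500), ankle_r = c(110, 500)))
  seq2$y[1, body25_index("ankle_l")] <- 5000
  expect_equal(estimate_height(seq2)$height, 500)
})

test_that("signal formulas reproduce hand-computed values", {
  # legs of length 2 (left) and 1 (right): R = 2/1 - 1/2
  seq <- toy_pose_seq(n = 2, kp = list(
    neck = c(0.5, -3),
    hip_l = c(0, 0), ankle_l = c(0, 2),
    hip_r = c(1, 0), ankle_r = c(1, 1),
    wrist_l = c(2, 1), wrist_r = c(0, 1),
    heel_l = c(0, 2), heel_r = c(1, 1)))
  sig <- compute_signal_set(seq)
  expect_equal(sig$r_legs, rep(1.5, 2))
  # equal-length legs give zero
  seq_sym <- toy_pose_seq(n = 2, kp = list(
    neck = c(0.5, -3),
    hip_l = c(0, 0), ankle_l = c(0, 2),
    hip_r = c(1, 0), ankle_r = c(1, 2),
    wrist_l = c(2, 1), wrist_r = c(0, 1),
    heel_l = c(0, 2), heel_r = c(1, 2)))
  sig_sym <- compute_signal_set(seq_sym)
  expect_equal(sig_sym$r_legs, rep(0, 2))
  # ankles at equal y: zero horizontal ankle angle;
  # neck vertically above the ankle midpoint: zero body angle
  expect_equal(sig_sym$a_ankles_horiz, rep(0, 2))
  expect_equal(sig_sym$a_body_vert, rep(0, 2))
  # wrists at equal y: zero wrist angle
  expect_equal(sig_sym$a_wrists_horiz, rep(0, 2))
})

test_that("heel distance is height-normalised as |x_L - x_R| / H", {
  # neck (145,140), ankle midpoint (145,300): H = 1.25 * 160 = 200
  seq <- toy_pose_seq(n = 4, kp = list(
    neck = c(145, 140), ankle_l = c(170, 300), ankle_r = c(120, 300),
    heel_l = c(170, 306), heel_r = c(120, 306),
    hip_l = c(160, 150), hip_r = c(130, 150),
    wrist_l = c(200, 160), wrist_r = c(90, 160)))
  sig <- compute_signal_set(seq)
  expect_equal(estimate_height(seq)$height, 200)
  expect_equal(sig$d_heels_horiz, rep(50 / 200, 4))  # = 0.25
  # stationary ankles: zero displacement signal of length n - 1
  expect_equal(sig$d_ankle_l, rep(0, 3))
  expect_equal(sig$d_ankle_r, rep(0, 3))
})

test_that("frames with missing required key-points are masked per signal", {
  seq <- toy_pose_seq(n = 5, kp = list(
    neck = c(100, 100), ankle_l = c(90, 500), ankle_r = c(110, 500),
    hip_l = c(95, 300), hip_r = c(105, 300),
    wrist_l = c(130, 250), wrist_r = c(70, 250),
    heel_l = c(90, 505), heel_r = c(110, 505)))
  seq$conf[3, body25_index("hip_l")] <- 0
  sig <- compute_signal_set(seq)
  expect_true(is.na(sig$r_legs[3]))
  expect_false(anyNA(sig$r_legs[-3]))
  expect_false(anyNA(sig$a_ankles_horiz))  # hips not required there
})

test_that("swapping left/right key-point labels negates the leg-ratio signal", {
  walk <- simulate_walk(gait_sim_params(duration = 4, seed = 21,
                                        keypoint_jitter_sd = 0,
                                        dropout_rate = 0))
  sig <- compute_signal_set(walk$sequence)
  sig_m <- compute_signal_set(mirror_pose_seq(walk$sequence))
  expect_equal(sig_m$r_legs, -sig$r_legs, tolerance = 1e-12)
})

test_that("signals are invariant to uniform scaling and translation", {
  walk <- simulate_walk(gait_sim_params(duration = 4, seed = 22,
                                        keypoint_jitter_sd = 0,
                                        dropout_rate = 0))
  seq <- walk$sequence
  sig <- compute_signal_set(seq)
  scaled <- seq
  scaled$x <- seq$x * 3 + 120
  scaled$y <- seq$y * 3 - 40
  sig_s <- compute_signal_set(scaled)
  for (s in c("r_legs", "a_body_vert", "a_ankles_horiz", "a_wrists_horiz",
              "d_heels_horiz", "d_ankle_l", "d_ankle_r")) {
    expect_equal(sig_s[[s]], sig[[s]], tolerance = 1e-9, label = s)
  }
})

test_that("a 10-cycle sine yields 10 alternating peaks and troughs", {
  t <- 0:299
  s <- sin(2 * pi * t / 30)
  ev <- detect_events(s, frame_rate = 30)
  expect_length(ev$peaks, 10L)
  expect_length(ev$troughs, 10L)
  merged <- sort(c(ev$peaks, ev$troughs))
  types <- ifelse(merged %in% ev$peaks, 1, -1)
  expect_true(all(diff(types) != 0))  # strict alternation

  # small white noise does not change the event counts
  set.seed(1)
  noisy <- s + rnorm(300, 0, 0.05)
  ev_n <- detect_events(noisy, frame_rate = 30)
  expect_length(ev_n$peaks, 10L)
  expect_length(ev_n$troughs, 10L)
})

test_that("flat and degenerate series produce no events", {
  expect_equal(detect_events(rep(1, 100), 30),
               list(peaks = integer(), troughs = integer()))
  expect_equal(detect_events(c(1, NA, 2, NA), 30),
               list(peaks = integer(), troughs = integer()))
})

test_that("detected event rate recovers the oscillation frequency", {
  for (f in c(0.6, 1.0, 1.5)) {
    t <- seq(0, 10, by = 1 / 30)
    s <- sin(2 * pi * f * t)
    ev <- detect_events(s, frame_rate = 30)
    n_events <- length(ev$peaks) + length(ev$troughs)
    expect_equal(n_events, 2 * f * 10, tolerance = 1.01 / (2 * f * 10),
                 label = sprintf("events at %.1f Hz", f))
  }
})

test_that("events are never placed on masked frames", {
  t <- 0:299
  s <- sin(2 * pi * t / 30)
  s[c(8, 38, 68)] <- NA  # mask some true-peak frames (t = 7.5 + 30k)
  ev <- detect_events(s, frame_rate = 30)
  expect_false(any(c(ev$peaks, ev$troughs) %in% c(8, 38, 68)))
})

test_that("long-format export carries all seven signals with validity flags", {
  walk <- simulate_walk(gait_sim_params(duration = 3, seed = 2))
  long <- signals_to_long(compute_signal_set(walk$sequence), roi_id = 2)
  expect_setequal(unique(long$signal_name),
                  c("r_legs", "a_body_vert", "a_ankles_horiz",
                    "a_wrists_horiz", "d_heels_horiz", "d_ankle_l",
                    "d_ankle_r"))
  expect_true(all(long$valid == is.finite(long$value)))
})
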