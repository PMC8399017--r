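# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# a clean 2 Hz, 10 s walk reused across modules
fixture_walk <- function() {
  if (is.null(.fixtures$walk)) {
    .fixtures$walk <- simulate_walk(gait_sim_params(
      step_frequency = 2, seed = 42, duration = 10))
  }
  .fixtures$walk
}

# a moderate synthetic cohort for model-level tests; mildly imbalanced but
# with every severity populated well enough for within-fold oversampling
fixture_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- simulate_cohort(
      n_videos = 100, class_probs = c(0.25, 0.30, 0.25, 0.20), seed = 11)
  }
  .fixtures$cohort
}

# pose sequence with every key-point fixed at given coordinates
# kp: named list of c(x, y); unnamed key-points sit at (0, 0) with conf 1
toy_pose_seq <- function(n = 5, kp = list(), frame_rate = 30) {
  x <- matrix(0, n, 25)
  y <- matrix(0, n, 25)
  conf <- matrix(1, n, 25)
  for (name in names(kp)) {
    j <- body25_index(name)
    x[, j] <- kp[[name]][1]
    y[, j] <- kp[[name]][2]
  }
  pose_sequence(x, y, conf, frame_rate = frame_rate, video_id = "toy")
}

# swap all left/right key-point labels of a pose sequence
mirror_pose_seq <- function(seq) {
  pairs <- rbind(
    c("shoulder_r", "shoulder_l"), c("elbow_r", "elbow_l"),
    c("wrist_r", "wrist_l"), c("hip_r", "hip_l"), c("knee_r", "knee_l"),
    c("ankle_r", "ankle_l"), c("eye_r", "eye_l"), c("ear_r", "ear_l"),
    c("big_toe_r", "big_toe_l"), c("small_toe_r", "small_toe_l"),
    c("heel_r", "heel_l"))
  perm <- seq_len(25)
  for (i in seq_len(nrow(pairs))) {
    a <- body25_index(pairs[i, 1]); b <- body25_index(pairs[i, 2])
    perm[c(a, b)] <- c(b, a)
  }
  out <- seq
  out$x <- seq$x[, perm]
  out$y <- seq$y[, perm]
  out$conf <- seq$conf[, perm]
  out$imputed <- seq$imputed[, perm]
  out
}

# cleanly separable 4-class feature table: one cluster per severity
separable_features <- function(n_per_class = 12, seed = 5) {
  set.seed(seed)
  centers <- matrix(c(2.2, 0.08, 0.60, 0.30, 0.20, 0.25,
                      1.8, 0.06, 0.40, 0.24, 0.35, 0.40,
                      1.5, 0.04, 0.25, 0.18, 0.50, 0.55,
                      1.2, 0.02, 0.10, 0.12, 0.65, 0.70),
                    nrow = 4, byrow = TRUE)
  labels <- rep(0:3, each = n_per_class)
  x <- centers[labels + 1, ] + matrix(rnorm(length(labels) * 6, 0, 0.005),
                                      ncol = 6)
  colnames(x) <- GAIT_FEATURES
  list(x = x, labels = labels,
       groups = paste0("v", seq_along(labels)))
}
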