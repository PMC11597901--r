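# Shared fixtures: small synthetic inputs built in code.

noise_free_obs <- function() {
  observation_model(keypoint_noise_sd = 0, depth_surface_bias = 0,
                    dropout_prob = 0)
}

# A static 17-keypoint "pose" held for a few frames (no walking), as a
# true-pose table usable by observe_markerless().
static_pose_table <- function(n_frames = 3, rate = 2) {
  m <- default_gait_model(1.0)
  a <- anthropometry()
  one <- skeleton_pose(m, a, 0)
  t <- (seq_len(n_frames) - 1) / rate
  out <- purrr::map_dfr(seq_len(n_frames), function(i) {
    tibble::tibble(frame = i, time_s = t[i], keypoint = one$keypoint,
                   x_m = one$x_m, y_m = one$y_m, z_m = one$z_m)
  })
  attr(out, "sample_rate") <- rate
  out
}

# Tiny two-camera keypoint CSV on disk; returns the path.
write_toy_keypoint_csv <- function(path = tempfile(fileext = ".csv"),
                                   confidence = 0.9) {
  kp <- coco17_keypoints()
  df <- tidyr::expand_grid(camera = c("a", "b"), frame = 1:3,
                           keypoint = kp)
  df$time_s <- (df$frame - 1) / 30
  df$x_m <- round(stats::runif(nrow(df)), 7)
  df$y_m <- round(stats::runif(nrow(df)), 7)
  df$z_m <- round(stats::runif(nrow(df)), 7)
  df$confidence <- confidence
  write_keypoint_table(df, path)
  path
}

# A small noise-free trial: returns the generate_study() row list element.
small_trial <- function(duration = 8, speed = 1.0, seed = 11,
                        obs = noise_free_obs()) {
  study <- generate_study(n_participants = 2, sessions = 1, speeds = speed,
                          obs_model = obs, seed = seed, duration = duration,
                          reference_noise_sd = 0)
  study$trial[[1]]
}
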