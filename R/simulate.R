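#' Anthropometry for the synthetic walker
#'
#' Segment lengths are expressed as fractions of stature (standard
#' anthropometric tables); the pelvis width is the hip-to-hip distance.
#'
#' @param stature Standing height in metres.
#' @param trunk_frac,thigh_frac,shank_frac Segment lengths as fractions of
#'   stature (hip-to-shoulder, hip-to-knee, knee-to-ankle).
#' @param pelvis_width Hip-to-hip distance in metres
#'   (default `0.13 * stature`).
#' @return A list with class `"anthropometry"`, lengths in metres.
#' @export
anthropometry <- function(stature = 1.75, trunk_frac = 0.288,
                          thigh_frac = 0.245, shank_frac = 0.246,
                          pelvis_width = 0.13 * stature) {
  check_number(stature, "stature", lower = 1e-6)
  for (f in c(trunk_frac, thigh_frac, shank_frac)) {
    check_number(f, "segment fraction", lower = 1e-6)
  }
  if (trunk_frac + thigh_frac + shank_frac >= 1) {
    stop_gv("Segment fractions must sum to less than 1.",
            class = "gaitverify_domain_error")
  }
  check_number(pelvis_width, "pelvis_width", lower = 1e-6)
  structure(list(stature = stature,
                 trunk = trunk_frac * stature,
                 thigh = thigh_frac * stature,
                 shank = shank_frac * stature,
                 pelvis_width = pelvis_width),
            class = "anthropometry")
}

#' Observation model for the markerless cameras
#'
#' Describes the error mechanisms applied when synthesising camera
#' observations of the true skeleton: isotropic Gaussian keypoint noise,
#' constant per-joint center offsets (mislocalization of joint centers by the
#' pose estimator, constant within a session), a depth-surface bias that
#' pulls every point toward the observing camera along the camera-to-point
#' ray (depth cameras see the body surface nearest the camera, not the
#' internal joint center), and random keypoint dropout.
#'
#' @param keypoint_noise_sd Isotropic noise standard deviation in metres
#'   (default 0.01; published pose/depth pipelines report no canonical value,
#'   so 10 mm is this simulator's choice of a realistic level).
#' @param joint_offsets Named list mapping keypoint names to length-3 offset
#'   vectors in metres (world frame), e.g.
#'   `list(right_hip = c(0.02, 0, 0.01))`. Empty by default.
#' @param depth_surface_bias Shift toward the camera in metres (default 0.02).
#' @param dropout_prob Probability that a keypoint detection is missing in a
#'   frame (default 0.02).
#' @param confidence_range Detections draw confidence uniformly from this
#'   range (dropped keypoints get confidence 0).
#' @param seed Optional integer; when set, observation functions reset the
#'   RNG so repeated calls reproduce byte-identical output.
#' @return A list with class `"observation_model"`.
#' @export
observation_model <- function(keypoint_noise_sd = 0.01,
                              joint_offsets = list(),
                              depth_surface_bias = 0.02,
                              dropout_prob = 0.02,
                              confidence_range = c(0.8, 1),
                              seed = NULL) {
  check_number(keypoint_noise_sd, "keypoint_noise_sd", lower = 0)
  check_number(depth_surface_bias, "depth_surface_bias", lower = 0)
  check_number(dropout_prob, "dropout_prob", lower = 0, upper = 1 - 1e-12)
  bad <- setdiff(names(joint_offsets), coco17_keypoints())
  if (length(bad) > 0L) {
    stop_gv(sprintf("joint_offsets has unknown keypoint name(s): %s.",
                    paste(bad, collapse = ", ")),
            class = "gaitverify_validation_error")
  }
  for (o in joint_offsets) {
    if (length(o) != 3L || anyNA(o)) {
      stop_gv("Each joint offset must be a finite length-3 vector (metres).",
              class = "gaitverify_validation_error")
    }
  }
  structure(list(keypoint_noise_sd = keypoint_noise_sd,
                 joint_offsets = joint_offsets,
                 depth_surface_bias = depth_surface_bias,
                 dropout_prob = dropout_prob,
                 confidence_range = confidence_range,
                 seed = seed),
            class = "observation_model")
}

#' Camera-to-world rotation aiming a camera at a target
#'
#' Camera z-axis toward `target`, x-axis horizontal, y = z cross x; columns
#' are the camera axes in world coordinates, so the matrix is camera-to-world
#' with determinant +1.
#'
#' @param position Camera position in world coordinates (metres).
#' @param target Point the camera looks at (default `c(0, 0, 1)`).
#' @return A 3x3 rotation matrix.
#' @export
look_at_rotation <- function(position, target = c(0, 0, 1)) {
  f <- target - position
  f <- f / sqrt(sum(f^2))
  x <- c(f[2], -f[1], 0)
  nx <- sqrt(sum(x^2))
  if (nx < 1e-9) stop_gv("Camera looking straight up/down is unsupported.")
  x <- x / nx
  y <- c(f[2] * x[3] - f[3] * x[2],
         f[3] * x[1] - f[1] * x[3],
         f[1] * x[2] - f[2] * x[1])
  R <- cbind(x, y, f)
  dimnames(R) <- NULL
  R
}

#' Default three-camera rig
#'
#' Cameras in front (+X), behind (-X) and to the right (-Y, with Y pointing
#' left) of the walker, 3 m away at 1.2 m height, all aimed at the subject.
#'
#' @param distance Horizontal distance from the subject in metres.
#' @param height Camera height in metres.
#' @return An [extrinsics_table()].
#' @export
default_extrinsics <- function(distance = 3, height = 1.2) {
  pos <- list(front = c(distance, 0, height),
              back = c(-distance, 0, height),
              right = c(0, -distance, height))
  extrinsics_table(
    camera = names(pos),
    rotation = lapply(pos, look_at_rotation),
    translation = pos
  )
}

# Fixed local offsets (metres) for head and arm keypoints, relative to the
# shoulder midline. Arms hang; the head sits above the shoulders.
head_arm_offsets <- function() {
  list(
    nose = c(0.10, 0, 0.18),
    left_eye = c(0.08, 0.03, 0.22), right_eye = c(0.08, -0.03, 0.22),
    left_ear = c(0.02, 0.07, 0.20), right_ear = c(0.02, -0.07, 0.20),
    left_elbow = c(0, 0.02, -0.28), right_elbow = c(0, -0.02, -0.28),
    left_wrist = c(0, 0.03, -0.54), right_wrist = c(0, -0.03, -0.54)
  )
}

#' True keypoint positions of the synthetic walker
#'
#' Forward kinematics of a sagittal-plane chain: the trunk segment runs
#' vertically from hip to shoulder, the thigh is rotated forward by the hip
#' flexion angle, and the shank is rotated back from the thigh by the knee
#' flexion angle, so that re-deriving the angles from the generated keypoints
#' with the vector method returns the model waveforms exactly. The left side
#' mirrors the right with a half-cycle phase shift. The whole body receives a
#' small rigid vertical/lateral oscillation (angle-invariant). World frame:
#' X = walking direction, Y = mediolateral (left positive), Z = up.
#'
#' @param model A [gait_model()].
#' @param anthro An [anthropometry()].
#' @param phase Numeric vector of gait phases.
#' @return A tibble `phase, keypoint, x_m, y_m, z_m` with
#'   `17 * length(phase)` rows.
#' @export
skeleton_pose <- function(model, anthro, phase) {
  stopifnot(inherits(model, "gait_model"), inherits(anthro, "anthropometry"))
  check_no_na(phase, "phase")
  phase <- phase %% 1

  deg2rad <- pi / 180
  hip_z0 <- anthro$thigh + anthro$shank + 0.09
  n <- length(phase)

  # rigid whole-body oscillation: two vertical bobs and one lateral sway
  # per cycle; a rigid translation leaves all joint angles unchanged
  body_dx <- 0.01 * sin(2 * pi * phase)
  body_dy <- 0.02 * sin(2 * pi * phase)
  body_dz <- 0.02 * cos(4 * pi * phase)

  idx <- seq_len(n)
  side_tbl <- purrr::map_dfr(c(right = -1, left = 1), function(sgn) {
    ph <- if (sgn < 0) phase else (phase + 0.5) %% 1
    h <- angle_at_phase(model, "hip", ph) * deg2rad
    k <- angle_at_phase(model, "knee", ph) * deg2rad
    side <- if (sgn < 0) "right" else "left"

    hip <- cbind(body_dx, body_dy + sgn * anthro$pelvis_width / 2,
                 body_dz + hip_z0)
    shoulder <- hip + cbind(0, 0, rep(anthro$trunk, n))
    knee <- hip + anthro$thigh * cbind(sin(h), 0, -cos(h))
    ankle <- knee + anthro$shank * cbind(sin(h - k), 0, -cos(h - k))

    tibble(
      .idx = rep(idx, 4),
      phase = rep(phase, 4),
      keypoint = rep(paste0(side, c("_shoulder", "_hip", "_knee", "_ankle")),
                     each = n),
      x_m = c(shoulder[, 1], hip[, 1], knee[, 1], ankle[, 1]),
      y_m = c(shoulder[, 2], hip[, 2], knee[, 2], ankle[, 2]),
      z_m = c(shoulder[, 3], hip[, 3], knee[, 3], ankle[, 3])
    )
  })

  # head and arms by fixed offsets from the shoulder midline
  neck <- cbind(body_dx, body_dy, body_dz + hip_z0 + anthro$trunk)
  scale <- anthro$stature / 1.75
  extra <- purrr::imap_dfr(head_arm_offsets(), function(off, kp) {
    base <- if (grepl("elbow|wrist", kp)) {
      sgn <- if (startsWith(kp, "left")) 1 else -1
      cbind(neck[, 1], neck[, 2] + sgn * anthro$pelvis_width / 2, neck[, 3])
    } else {
      neck
    }
    tibble(.idx = idx, phase = phase, keypoint = kp,
           x_m = base[, 1] + off[1] * scale,
           y_m = base[, 2] + off[2] * scale,
           z_m = base[, 3] + off[3] * scale)
  })

  out <- dplyr::bind_rows(side_tbl, extra)
  out$keypoint <- factor(out$keypoint, levels = coco17_keypoints())
  out <- dplyr::arrange(out, .data$.idx, .data$keypoint)
  out$keypoint <- as.character(out$keypoint)
  out$.idx <- NULL
  out
}

#' Sample the true skeleton over time
#'
#' Evaluates [skeleton_pose()] on a uniform time grid, with phase
#' `(t / cycle_duration) mod 1` so ground-truth cycle starts fall at integer
#' multiples of the cycle duration.
#'
#' @param model A [gait_model()].
#' @param anthro An [anthropometry()].
#' @param duration Trial length in seconds.
#' @param rate Sampling rate in Hz.
#' @return A tibble `frame, time_s, keypoint, x_m, y_m, z_m` with attribute
#'   `sample_rate`.
#' @export
pose_series <- function(model, anthro, duration, rate = 90) {
  check_number(duration, "duration", lower = 1e-9)
  check_number(rate, "rate", lower = 1e-9)
  t <- seq(0, duration, by = 1 / rate)
  poses <- skeleton_pose(model, anthro, t / model$cycle_duration)
  n_kp <- 17L
  out <- tibble(
    frame = rep(seq_along(t), each = n_kp),
    time_s = rep(t, each = n_kp),
    keypoint = poses$keypoint,
    x_m = poses$x_m, y_m = poses$y_m, z_m = poses$z_m
  )
  attr(out, "sample_rate") <- rate
  out
}

#' Synthesise markerless camera observations
#'
#' For each camera: samples the true poses on the camera's time grid, applies
#' the constant per-joint center offsets, pulls every point toward the camera
#' by the depth-surface bias, expresses the result in the camera frame, adds
#' isotropic Gaussian noise, and drops keypoints at random (absent
#' coordinates, confidence 0). With all error magnitudes zero the
#' observations equal the sampled truth exactly.
#'
#' @param true_poses Output of [pose_series()] (or same layout with a
#'   `sample_rate` attribute).
#' @param extrinsics An [extrinsics_table()]; one output stream per row.
#' @param obs_model An [observation_model()].
#' @param rate Camera rate in Hz (default 30); must not exceed the truth rate.
#' @return A keypoint tibble (long layout, `ref_frame = "camera"`) covering
#'   all cameras.
#' @export
observe_markerless <- function(true_poses, extrinsics, obs_model, rate = 30) {
  check_cols(true_poses, c("frame", "time_s", "keypoint", "x_m", "y_m", "z_m"),
             "true_poses")
  stopifnot(inherits(obs_model, "observation_model"))
  true_rate <- attr(true_poses, "sample_rate") %||%
    infer_rate(unique(true_poses$time_s), what = "true_poses")
  if (rate > true_rate + 1e-9) {
    stop_gv(sprintf(
      "Requested camera rate %g Hz exceeds the true-pose rate %g Hz.",
      rate, true_rate),
      class = "gaitverify_resampling_error")
  }
  if (nrow(extrinsics) < 1L) {
    stop_gv("At least one camera is required.",
            class = "gaitverify_domain_error")
  }
  if (!is.null(obs_model$seed)) set.seed(obs_model$seed)

  t_true <- sort(unique(true_poses$time_s))
  t_cam <- seq(min(t_true), max(t_true), by = 1 / rate)

  # truth resampled once onto the camera grid (linear interpolation; exact
  # when the camera grid is a subset of the truth grid)
  kps <- coco17_keypoints()
  sampled <- purrr::map_dfr(kps, function(kp) {
    sub <- true_poses[true_poses$keypoint == kp, ]
    tibble(keypoint = kp, time_s = t_cam,
           x_m = approx(sub$time_s, sub$x_m, t_cam)$y,
           y_m = approx(sub$time_s, sub$y_m, t_cam)$y,
           z_m = approx(sub$time_s, sub$z_m, t_cam)$y)
  })

  # constant per-joint center offsets (world frame)
  for (kp in names(obs_model$joint_offsets)) {
    off <- obs_model$joint_offsets[[kp]]
    i <- sampled$keypoint == kp
    sampled$x_m[i] <- sampled$x_m[i] + off[1]
    sampled$y_m[i] <- sampled$y_m[i] + off[2]
    sampled$z_m[i] <- sampled$z_m[i] + off[3]
  }

  frame_of <- match(sampled$time_s, t_cam)

  purrr::map_dfr(seq_len(nrow(extrinsics)), function(ci) {
    row <- extrinsics[ci, ]
    R <- extrinsics_rotation(row)
    tr <- extrinsics_translation(row)

    px <- sampled$x_m
    py <- sampled$y_m
    pz <- sampled$z_m
    if (obs_model$depth_surface_bias > 0) {
      dx <- tr[1] - px
      dy <- tr[2] - py
      dz <- tr[3] - pz
      d <- sqrt(dx^2 + dy^2 + dz^2)
      px <- px + obs_model$depth_surface_bias * dx / d
      py <- py + obs_model$depth_surface_bias * dy / d
      pz <- pz + obs_model$depth_surface_bias * dz / d
    }
    # camera frame: p_cam = R^T (p_world - t)
    qx <- px - tr[1]; qy <- py - tr[2]; qz <- pz - tr[3]
    cx <- R[1, 1] * qx + R[2, 1] * qy + R[3, 1] * qz
    cy <- R[1, 2] * qx + R[2, 2] * qy + R[3, 2] * qz
    cz <- R[1, 3] * qx + R[2, 3] * qy + R[3, 3] * qz

    m <- length(cx)
    if (obs_model$keypoint_noise_sd > 0) {
      cx <- cx + rnorm(m, sd = obs_model$keypoint_noise_sd)
      cy <- cy + rnorm(m, sd = obs_model$keypoint_noise_sd)
      cz <- cz + rnorm(m, sd = obs_model$keypoint_noise_sd)
    }
    conf <- runif(m, obs_model$confidence_range[1],
                  obs_model$confidence_range[2])
    if (obs_model$dropout_prob > 0) {
      dropped <- runif(m) < obs_model$dropout_prob
      cx[dropped] <- NA_real_
      cy[dropped] <- NA_real_
      cz[dropped] <- NA_real_
      conf[dropped] <- 0
    }

    out <- tibble(camera = row$camera,
                  frame = frame_of,
                  time_s = sampled$time_s,
                  keypoint = sampled$keypoint,
                  x_m = cx, y_m = cy, z_m = cz,
                  confidence = conf,
                  ref_frame = "camera")
    dplyr::arrange(out, .data$time_s, .data$keypoint)
  })
}

#' Ground-truth joint angle waveforms
#'
#' @param model A [gait_model()].
#' @param duration Trial length in seconds.
#' @param rate Sampling rate in Hz (default 100).
#' @return A long tibble `time_s, joint, angle_deg` with attribute
#'   `sample_rate`.
#' @export
true_angle_waveform <- function(model, duration, rate = 100) {
  t <- seq(0, duration, by = 1 / rate)
  phi <- t / model$cycle_duration
  out <- purrr::map_dfr(names(model$coefficients), function(j) {
    tibble(time_s = t, joint = j, angle_deg = angle_at_phase(model, j, phi))
  })
  attr(out, "sample_rate") <- rate
  out
}

#' Synthesise reference-system angle waveforms
#'
#' Emulates the marker-based reference stream: the true waveform resampled to
#' the reference rate plus i.i.d. Gaussian noise and an optional constant
#' offset (residual marker-placement/model bias).
#'
#' @param true_angles Long tibble `time_s, joint, angle_deg` (e.g. from
#'   [true_angle_waveform()]).
#' @param noise_sd Angular noise standard deviation in degrees.
#' @param rate Output rate in Hz (default 100).
#' @param offset_deg Constant offset added to every sample (default 0).
#' @param seed Optional integer RNG seed.
#' @return A long tibble `time_s, joint, angle_deg` with attribute
#'   `sample_rate`.
#' @export
observe_reference <- function(true_angles, noise_sd = 0, rate = 100,
                              offset_deg = 0, seed = NULL) {
  check_cols(true_angles, c("time_s", "joint", "angle_deg"), "true_angles")
  check_number(noise_sd, "noise_sd", lower = 0)
  if (!is.null(seed)) set.seed(seed)
  t_out <- seq(min(true_angles$time_s), max(true_angles$time_s), by = 1 / rate)
  out <- purrr::map_dfr(unique(true_angles$joint), function(j) {
    sub <- true_angles[true_angles$joint == j, ]
    v <- approx(sub$time_s, sub$angle_deg, t_out)$y
    tibble(time_s = t_out, joint = j,
           angle_deg = v + offset_deg +
             (if (noise_sd > 0) rnorm(length(v), sd = noise_sd) else 0))
  })
  attr(out, "sample_rate") <- rate
  out
}

#' Synthesise a vertical ground-reaction-force series
#'
#' Zero during swing, a positive double-bump profile during stance, with the
#' rising zero crossing exactly at each ground-truth heel strike (cycle
#' start). The onset rises steeply (square-root shape) so a small detection
#' threshold is reached within a millisecond of the true event.
#'
#' @param model A [gait_model()].
#' @param duration Trial length in seconds (at least one cycle).
#' @param rate Sampling rate in Hz (default 1000).
#' @param body_mass Body mass in kg (default 70), scaling the force.
#' @return A tibble `time_s, fz_N` with attribute `sample_rate`.
#' @export
synth_grf <- function(model, duration, rate = 1000, body_mass = 70) {
  if (duration < model$cycle_duration) {
    stop_gv("`duration` must cover at least one gait cycle.",
            class = "gaitverify_domain_error")
  }
  t <- seq(0, duration, by = 1 / rate)
  phi <- (t / model$cycle_duration) %% 1
  u <- phi / model$stance_fraction # within-stance coordinate
  in_stance <- u < 1
  f <- numeric(length(t))
  uu <- u[in_stance]
  f[in_stance] <- 1.25 * body_mass * 9.81 *
    sqrt(sin(pi * uu)) * (0.75 + 0.5 * abs(cos(pi * uu)))
  out <- tibble(time_s = t, fz_N = pmax(f, 0))
  attr(out, "sample_rate") <- rate
  out
}

#' Generate a complete synthetic validation study
#'
#' Emulates a two-session, multi-speed treadmill study: per-participant
#' anthropometry and waveform perturbations are drawn once; session 2 re-uses
#' the participant's parameters with a small session-level perturbation
#' (test-retest structure). Perturbations are amplitude-scale-plus-offset
#' transforms, so the knee-minimum anchor at phase 0 is preserved exactly and
#' ground-truth cycle starts remain at integer multiples of the cycle
#' duration. All randomness flows from `seed`.
#'
#' @param n_participants Number of participants (default 15).
#' @param sessions Number of sessions (default 2).
#' @param speeds Treadmill speeds in m/s (default `c(0.7, 1.0, 1.3)`).
#' @param obs_model An [observation_model()] for the markerless cameras.
#' @param seed Integer seed for all randomness.
#' @param duration Trial length in seconds (default 60).
#' @param extrinsics Camera rig (default [default_extrinsics()]).
#' @param truth_rate Sampling rate of the internal true-pose stream
#'   (default 90 Hz, an exact multiple of the 30 Hz camera rate).
#' @param reference_noise_sd Reference-stream angular noise, degrees.
#' @param participant_amp_sd,participant_offset_sd,participant_cycle_sd
#'   Between-participant perturbation scales (amplitude factor SD, waveform
#'   offset SD in degrees, cycle-duration factor SD).
#' @param session_amp_sd,session_offset_sd Session-2 perturbation scales,
#'   small by default so that a session-2 waveform differs from session 1 by
#'   well under a degree on average.
#' @return A tibble `participant, session, speed, trial` where `trial` is a
#'   list column of `"gait_trial"` objects: observed streams (`markerless`,
#'   `reference`, `grf`, `extrinsics`) plus ground truth (`model`, `anthro`,
#'   `cycle_starts`, `true_angles`, `true_params`).
#' @export
generate_study <- function(n_participants = 15, sessions = 2,
                           speeds = c(0.7, 1.0, 1.3),
                           obs_model = observation_model(),
                           seed = 1,
                           duration = 60,
                           extrinsics = default_extrinsics(),
                           truth_rate = 90,
                           reference_noise_sd = 0.3,
                           participant_amp_sd = 0.07,
                           participant_offset_sd = 2,
                           participant_cycle_sd = 0.04,
                           session_amp_sd = 0.015,
                           session_offset_sd = 0.3) {
  if (n_participants < 2) {
    stop_gv("At least 2 participants are required for downstream statistics.",
            class = "gaitverify_domain_error")
  }
  if (!sessions %in% seq_len(10L)) {
    stop_gv("`sessions` must be a small positive integer.",
            class = "gaitverify_domain_error")
  }
  set.seed(seed)

  base_models <- lapply(speeds, default_gait_model)
  names(base_models) <- as.character(speeds)

  grid <- tidyr::expand_grid(participant = seq_len(n_participants),
                             session = seq_len(sessions),
                             speed = speeds)

  # participant-level draws (shared across sessions and speeds)
  part <- lapply(seq_len(n_participants), function(p) {
    list(stature = rnorm(1, 1.75, 0.10),
         mass = rnorm(1, 70, 12),
         amp = c(hip = rnorm(1, 1, participant_amp_sd),
                 knee = rnorm(1, 1, participant_amp_sd)),
         offset = c(hip = rnorm(1, 0, participant_offset_sd),
                    knee = rnorm(1, 0, participant_offset_sd)),
         cycle = rnorm(1, 1, participant_cycle_sd))
  })
  # session-level draws (shared across speeds; session 1 is the baseline)
  sess <- lapply(seq_len(n_participants), function(p) {
    lapply(seq_len(sessions), function(s) {
      if (s == 1) {
        list(amp = c(hip = 1, knee = 1), offset = c(hip = 0, knee = 0),
             cycle = 1)
      } else {
        list(amp = c(hip = rnorm(1, 1, session_amp_sd),
                     knee = rnorm(1, 1, session_amp_sd)),
             offset = c(hip = rnorm(1, 0, session_offset_sd),
                        knee = rnorm(1, 0, session_offset_sd)),
             cycle = rnorm(1, 1, 0.01))
      }
    })
  })

  trials <- purrr::pmap(grid, function(participant, session, speed) {
    pp <- part[[participant]]
    ss <- sess[[participant]][[session]]
    model <- perturb_gait_model(
      base_models[[as.character(speed)]],
      scale = pp$amp * ss$amp,
      offset = pp$offset + ss$offset,
      cycle_scale = pp$cycle * ss$cycle
    )
    anthro <- anthropometry(stature = max(1.4, pp$stature))

    poses <- pose_series(model, anthro, duration, rate = truth_rate)
    markerless <- observe_markerless(poses, extrinsics, obs_model, rate = 30)
    true_angles <- true_angle_waveform(model, duration, rate = 100)
    reference <- observe_reference(true_angles, noise_sd = reference_noise_sd,
                                   rate = 100)
    grf <- synth_grf(model, duration, rate = 1000,
                     body_mass = max(45, pp$mass))

    structure(
      list(participant = participant, session = session, speed = speed,
           markerless = markerless, reference = reference, grf = grf,
           extrinsics = extrinsics,
           model = model, anthro = anthro,
           cycle_starts = seq(0, duration, by = model$cycle_duration),
           true_angles = true_angles,
           true_params = true_discrete_params(model)),
      class = "gait_trial")
  })

  grid$trial <- trials
  grid
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf(
    "<gait_trial> participant %s, session %d, speed %.1f m/s\n",
    x$participant, x$session, x$speed))
  cat(sprintf("  markerless: %d cameras, %d frames at 30 Hz\n",
              length(unique(x$markerless$camera)),
              length(unique(x$markerless$time_s))))
  cat(sprintf("  reference:  %d samples at 100 Hz; GRF: %d samples\n",
              length(unique(x$reference$time_s)), nrow(x$grf)))
  cat(sprintf("  truth: cycle %.3f s, %d cycle starts\n",
              x$model$cycle_duration, length(x$cycle_starts)))
  invisible(x)
}
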