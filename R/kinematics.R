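#' Transform camera-frame keypoints to the world frame
#'
#' Applies the rigid camera-to-world transform `p_world = R p_cam + t` to
#' every detection, camera by camera.
#'
#' @param frames Keypoint tibble in the camera frame (long layout with a
#'   `ref_frame` column equal to `"camera"`).
#' @param extrinsics An [extrinsics_table()] covering every camera present.
#' @return The keypoint tibble with world coordinates and
#'   `ref_frame = "world"`.
#' @export
to_world <- function(frames, extrinsics) {
  check_cols(frames, c("camera", "keypoint", "x_m", "y_m", "z_m"), "frames")
  if ("ref_frame" %in% names(frames) && any(frames$ref_frame == "world")) {
    stop_gv("`frames` is already in the world frame.",
            class = "gaitverify_domain_error")
  }
  missing_cam <- setdiff(unique(frames$camera), extrinsics$camera)
  if (length(missing_cam) > 0L) {
    stop_gv(sprintf("No extrinsics for camera(s): %s.",
                    paste(missing_cam, collapse = ", ")),
            class = "gaitverify_validation_error")
  }
  out <- frames
  for (cam in unique(frames$camera)) {
    row <- extrinsics[extrinsics$camera == cam, ]
    R <- extrinsics_rotation(row)
    tr <- extrinsics_translation(row)
    i <- which(out$camera == cam)
    x <- out$x_m[i]; y <- out$y_m[i]; z <- out$z_m[i]
    out$x_m[i] <- R[1, 1] * x + R[1, 2] * y + R[1, 3] * z + tr[1]
    out$y_m[i] <- R[2, 1] * x + R[2, 2] * y + R[2, 3] * z + tr[2]
    out$z_m[i] <- R[3, 1] * x + R[3, 2] * y + R[3, 3] * z + tr[3]
  }
  out$ref_frame <- "world"
  out
}

#' Fuse multi-camera keypoints into a single skeleton stream
#'
#' Per keypoint and frame, cameras whose detection lies farther than `gate`
#' metres from the per-keypoint median position are excluded, and the
#' remaining detections are combined by a confidence-weighted mean. A
#' keypoint is absent in a frame when no camera survives. Fusing a single
#' camera returns its stream unchanged.
#'
#' @param world_frames Keypoint tibble in the world frame (all cameras,
#'   aligned timestamps and a common rate).
#' @param gate Outlier gate distance in metres (default 0.15).
#' @return A tibble `frame, time_s, keypoint, x_m, y_m, z_m, n_cameras,
#'   weight_sum` with one row per keypoint per frame, plus attribute
#'   `sample_rate`.
#' @export
fuse_keypoints <- function(world_frames, gate = 0.15) {
  check_cols(world_frames,
             c("camera", "frame", "time_s", "keypoint", "x_m", "y_m", "z_m",
               "confidence"), "world_frames")
  if ("ref_frame" %in% names(world_frames) &&
      any(world_frames$ref_frame != "world")) {
    stop_gv("`world_frames` must be in the world frame (apply to_world()).",
            class = "gaitverify_domain_error")
  }
  cams <- sort(unique(world_frames$camera))
  n_cam <- length(cams)

  # common grid: overlap is required; cameras are assumed frame-aligned
  times_by_cam <- lapply(cams, function(cm)
    unique(world_frames$time_s[world_frames$camera == cm]))
  t0 <- max(vapply(times_by_cam, min, numeric(1)))
  t1 <- min(vapply(times_by_cam, max, numeric(1)))
  if (t0 > t1) {
    stop_gv("Cameras share no overlapping time support.",
            class = "gaitverify_validation_error")
  }
  t_grid <- sort(unique(world_frames$time_s))
  t_grid <- t_grid[t_grid >= t0 & t_grid <= t1]
  rate <- infer_rate(t_grid, what = "fused stream")
  kps <- sort(unique(world_frames$keypoint))

  # aligned (grid x camera) matrices per coordinate; rows indexed by
  # (time, keypoint) pairs
  n_kp <- length(kps)
  n_grid <- length(t_grid) * n_kp
  X <- Y <- Z <- W <- matrix(NA_real_, nrow = n_grid, ncol = n_cam)
  for (ci in seq_len(n_cam)) {
    sub <- world_frames[world_frames$camera == cams[ci], ]
    ti <- match(sub$time_s, t_grid)
    ki <- match(sub$keypoint, kps)
    ok <- !is.na(ti)
    idx <- (ti[ok] - 1L) * n_kp + ki[ok]
    X[idx, ci] <- sub$x_m[ok]
    Y[idx, ci] <- sub$y_m[ok]
    Z[idx, ci] <- sub$z_m[ok]
    W[idx, ci] <- sub$confidence[ok]
  }
  # treat absent coordinates as absent detections regardless of confidence
  W[is.na(X) | is.na(Y) | is.na(Z)] <- NA_real_

  med_x <- row_median(X)
  med_y <- row_median(Y)
  med_z <- row_median(Z)
  dist <- sqrt((X - med_x)^2 + (Y - med_y)^2 + (Z - med_z)^2)
  Wg <- W
  Wg[is.na(dist) | dist > gate] <- NA_real_
  # zero-confidence survivors still count: floor weights at a small value
  Wg[!is.na(Wg) & Wg <= 0] <- 1e-6

  wsum <- rowSums(Wg, na.rm = TRUE)
  fuse1 <- function(M) {
    v <- rowSums(M * Wg, na.rm = TRUE) / wsum
    v[wsum == 0] <- NA_real_
    v
  }
  out <- tibble(
    frame = rep(seq_along(t_grid), each = length(kps)),
    time_s = rep(t_grid, each = length(kps)),
    keypoint = rep(kps, length(t_grid)),
    x_m = fuse1(X), y_m = fuse1(Y), z_m = fuse1(Z),
    n_cameras = rowSums(!is.na(Wg)),
    weight_sum = wsum
  )
  attr(out, "sample_rate") <- rate
  out
}

# Row-wise median of a matrix with NA removal; closed form for <= 3 columns
# on complete rows, generic fallback elsewhere.
row_median <- function(M) {
  n_col <- ncol(M)
  if (n_col == 1L) return(M[, 1])
  has_na <- rowSums(is.na(M)) > 0
  out <- numeric(nrow(M))
  if (n_col == 2L) {
    out <- rowMeans(M, na.rm = TRUE)
  } else if (n_col == 3L) {
    cmpl <- !has_na
    out[cmpl] <- M[cmpl, 1] + M[cmpl, 2] + M[cmpl, 3] -
      pmax(M[cmpl, 1], M[cmpl, 2], M[cmpl, 3]) -
      pmin(M[cmpl, 1], M[cmpl, 2], M[cmpl, 3])
    if (any(has_na)) {
      out[has_na] <- apply(M[has_na, , drop = FALSE], 1, median, na.rm = TRUE)
    }
  } else {
    out <- apply(M, 1, median, na.rm = TRUE)
  }
  out[rowSums(!is.na(M)) == 0] <- NA_real_
  out
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a Butterworth low-pass filter and applies it forward and backward
#' (zero phase, no lag), the standard smoothing for kinematic trajectories.
#' DC is preserved exactly up to floating point.
#'
#' @param x Uniformly sampled numeric series (no NA).
#' @param fs Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz (default 6); must be below `fs / 2`.
#' @param order Filter order (default 4) before the bidirectional pass.
#' @return The filtered series, same length as `x`.
#' @export
lowpass <- function(x, fs, cutoff = 6, order = 4) {
  check_number(fs, "fs", lower = 1e-9)
  check_number(cutoff, "cutoff", lower = 1e-12)
  if (cutoff >= fs / 2) {
    stop_gv(sprintf("Cutoff %g Hz is at or above the Nyquist rate %g Hz.",
                    cutoff, fs / 2),
            class = "gaitverify_domain_error")
  }
  check_no_na(x, "x")
  if (length(x) <= 3 * order) {
    stop_gv(sprintf(
      "Series of length %d is too short for zero-phase order-%d filtering.",
      length(x), order),
      class = "gaitverify_domain_error")
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # remove the mean before filtering to curb edge transients, restore after
  mu <- mean(x)
  signal::filtfilt(bf, x - mu) + mu
}

#' Signed flexion angle at a joint from three points
#'
#' Projects the vectors from the vertex to `a` and to `b` onto the plane
#' orthogonal to `sagittal_normal` and returns `180 - included angle` in
#' degrees: 0 when `a`, `vertex`, `b` are collinear (full extension),
#' positive when the cross product `(a - vertex) x (b - vertex)` points along
#' `sagittal_normal`. With the world convention X = walking direction and
#' Y = left, the right-side calls `flexion_angle(shoulder, hip, knee, c(0,1,0))`
#' and `flexion_angle(ankle, knee, hip, c(0,1,0))` make flexion positive.
#'
#' @param a,vertex,b Numeric length-3 points, or matrices with 3 columns for
#'   a vectorized call (one row per frame).
#' @param sagittal_normal Unit normal of the sagittal plane (default
#'   `c(0, 1, 0)`).
#' @param project If `FALSE`, skip the sagittal projection and use the full
#'   3D included angle (sign still taken from the cross product component).
#' @return Flexion angle(s) in degrees.
#' @export
flexion_angle <- function(a, vertex, b, sagittal_normal = c(0, 1, 0),
                          project = TRUE) {
  as_mat <- function(p) {
    if (is.matrix(p)) p else matrix(p, ncol = 3)
  }
  a <- as_mat(a); vertex <- as_mat(vertex); b <- as_mat(b)
  nrm <- sagittal_normal / sqrt(sum(sagittal_normal^2))

  u <- a - vertex
  w <- b - vertex
  if (project) {
    u <- u - (u %*% nrm) %*% t(nrm)
    w <- w - (w %*% nrm) %*% t(nrm)
  }
  nu <- sqrt(rowSums(u^2))
  nw <- sqrt(rowSums(w^2))
  if (any(nu < 1e-12 | nw < 1e-12, na.rm = TRUE)) {
    stop_gv("Degenerate geometry: zero-length (projected) segment vector.",
            class = "gaitverify_degenerate_error")
  }
  cosang <- pmin(1, pmax(-1, rowSums(u * w) / (nu * nw)))
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sgn <- sign(cx * nrm[1] + cy * nrm[2] + cz * nrm[3])
  sgn[sgn == 0] <- 1
  ang <- (180 - acos(cosang) * 180 / pi) * sgn
  if (length(ang) == 1L) as.numeric(ang) else ang
}

#' Hip and knee flexion waveforms from a fused skeleton stream
#'
#' Extracts the side's shoulder, hip, knee and ankle trajectories, linearly
#' interpolates gaps of up to `max_gap` frames, low-pass filters the raw
#' keypoint trajectories (not the angles), and computes the vector-method
#' flexion angles: hip from (shoulder, hip, knee), knee from
#' (hip, knee, ankle).
#'
#' @param skel Fused skeleton tibble from [fuse_keypoints()] (long layout
#'   `time_s, keypoint, x_m, y_m, z_m`, uniform rate).
#' @param side `"right"` (default) or `"left"`.
#' @param cfg A [stats_config()] providing the filter design.
#' @param max_gap Longest keypoint gap (frames) bridged by interpolation.
#' @param min_presence Minimum fraction of frames in which each required
#'   keypoint must be present.
#' @param hip_reference `"same_side_shoulder"` (default) or
#'   `"shoulder_midpoint"` for the trunk landmark of the hip angle.
#' @param project Passed to [flexion_angle()]; `FALSE` uses unprojected 3D
#'   included angles.
#' @return A long tibble `time_s, joint, angle_deg` (`joint` in hip, knee)
#'   with attribute `sample_rate`.
#' @export
angles_from_skeleton <- function(skel, side = c("right", "left"),
                                 cfg = stats_config(),
                                 max_gap = 3L,
                                 min_presence = 0.9,
                                 hip_reference = c("same_side_shoulder",
                                                   "shoulder_midpoint"),
                                 project = TRUE) {
  side <- match.arg(side)
  hip_reference <- match.arg(hip_reference)
  check_cols(skel, c("time_s", "keypoint", "x_m", "y_m", "z_m"), "skel")

  need <- paste0(side, c("_shoulder", "_hip", "_knee", "_ankle"))
  if (hip_reference == "shoulder_midpoint") {
    need <- union(need, c("left_shoulder", "right_shoulder"))
  }
  t_grid <- sort(unique(skel$time_s))
  rate <- infer_rate(t_grid, what = "skeleton stream")

  traj <- list()
  too_missing <- character(0)
  for (kp in need) {
    sub <- skel[skel$keypoint == kp, ]
    m <- cbind(sub$x_m[match(t_grid, sub$time_s)],
               sub$y_m[match(t_grid, sub$time_s)],
               sub$z_m[match(t_grid, sub$time_s)])
    if (mean(stats::complete.cases(m)) < min_presence) {
      too_missing <- c(too_missing, kp)
      next
    }
    m <- apply(m, 2, function(col)
      zoo::na.approx(col, maxgap = max_gap, na.rm = FALSE, rule = 2))
    if (anyNA(m)) {
      too_missing <- c(too_missing, kp)
      next
    }
    traj[[kp]] <- apply(m, 2, lowpass, fs = rate,
                        cutoff = cfg$filter_cutoff, order = cfg$filter_order)
  }
  if (length(too_missing) > 0L) {
    stop_gv(sprintf(
      "Excessive missingness (>%d-frame gaps or <%g%% presence) for: %s.",
      max_gap, 100 * min_presence, paste(too_missing, collapse = ", ")),
      class = "gaitverify_missingness_error")
  }

  # both legs flex about the same mediolateral axis: one sagittal normal
  nrm <- c(0, 1, 0)
  trunk_ref <- if (hip_reference == "same_side_shoulder") {
    traj[[paste0(side, "_shoulder")]]
  } else {
    (traj[["left_shoulder"]] + traj[["right_shoulder"]]) / 2
  }
  hip <- traj[[paste0(side, "_hip")]]
  knee <- traj[[paste0(side, "_knee")]]
  ankle <- traj[[paste0(side, "_ankle")]]

  hip_angle <- flexion_angle(trunk_ref, hip, knee, nrm, project = project)
  knee_angle <- flexion_angle(ankle, knee, hip, nrm, project = project)

  out <- dplyr::bind_rows(
    tibble(time_s = t_grid, joint = "hip", angle_deg = hip_angle),
    tibble(time_s = t_grid, joint = "knee", angle_deg = knee_angle)
  )
  attr(out, "sample_rate") <- rate
  out
}

#' Full markerless kinematics: cameras to angle waveforms
#'
#' Convenience wrapper chaining [to_world()], [fuse_keypoints()] and
#' [angles_from_skeleton()].
#'
#' @param frames Multi-camera keypoint tibble in the camera frame.
#' @param extrinsics An [extrinsics_table()].
#' @param cfg A [stats_config()].
#' @param gate Fusion outlier gate in metres.
#' @param ... Passed to [angles_from_skeleton()].
#' @return A long angle tibble (`time_s, joint, angle_deg`).
#' @export
markerless_angles <- function(frames, extrinsics, cfg = stats_config(),
                              gate = 0.15, ...) {
  frames %>%
    to_world(extrinsics) %>%
    fuse_keypoints(gate = gate) %>%
    angles_from_skeleton(cfg = cfg, ...)
}
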