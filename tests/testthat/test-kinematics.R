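test_that("to_world applies the rigid transform and tracks the frame flag", {
  df <- tibble::tibble(camera = "c1", frame = 1L, time_s = 0,
                       keypoint = "right_hip", x_m = 1, y_m = 0, z_m = 0,
                       confidence = 1, ref_frame = "camera")
  ident <- extrinsics_table("c1", list(diag(3)), list(c(0, 0, 0)))
  out <- to_world(df, ident)
  expect_equal(c(out$x_m, out$y_m, out$z_m), c(1, 0, 0))
  expect_equal(out$ref_frame, "world")

  shift <- extrinsics_table("c1", list(diag(3)), list(c(1, 0, 0)))
  expect_equal(to_world(df, shift)$x_m, 2)

  rz90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  rot <- extrinsics_table("c1", list(rz90), list(c(0, 0, 0)))
  out <- to_world(df, rot)
  expect_equal(c(out$x_m, out$y_m, out$z_m), c(0, 1, 0), tolerance = 1e-12)

  expect_error(to_world(out, ident), class = "gaitverify_domain_error")
})

test_that("fusion averages concordant cameras and gates outliers", {
  mk <- function(cam, x, conf = 1) {
    tibble::tibble(camera = cam, frame = 1:2, time_s = c(0, 1 / 30),
                   keypoint = "right_knee", x_m = x, y_m = 0, z_m = 0,
                   confidence = conf, ref_frame = "world")
  }
  # all cameras identical -> that point, all cameras used
  f <- fuse_keypoints(dplyr::bind_rows(mk("a", 0), mk("b", 0), mk("c", 0)))
  expect_equal(f$x_m, c(0, 0))
  expect_equal(f$n_cameras, c(3, 3))

  # one camera missing the keypoint -> mean of the remaining two
  two <- dplyr::bind_rows(mk("a", 0.1), mk("b", 0.3))
  f2 <- fuse_keypoints(two)
  expect_equal(f2$x_m, c(0.2, 0.2))

  # outlier camera beyond the gate is excluded
  f3 <- fuse_keypoints(dplyr::bind_rows(mk("a", 0), mk("b", 0), mk("c", 1)),
                       gate = 0.5)
  expect_equal(f3$x_m, c(0, 0))
  expect_equal(f3$n_cameras, c(2, 2))

  # confidence-weighted mean within the gate
  f4 <- fuse_keypoints(dplyr::bind_rows(mk("a", 0, conf = 3 / 4),
                                        mk("b", 0.1, conf = 1 / 4)),
                       gate = 1)
  expect_equal(f4$x_m, c(0.025, 0.025))

  # fusing a single camera is the identity on positions
  one <- mk("solo", c(0.11, 0.22))
  f5 <- fuse_keypoints(one)
  expect_equal(f5$x_m, one$x_m)

  # disjoint time support is an error
  late <- mk("b", 0)
  late$time_s <- late$time_s + 100
  expect_error(fuse_keypoints(dplyr::bind_rows(mk("a", 0), late)),
               class = "gaitverify_validation_error")
})

test_that("zero-phase Butterworth has the analytic magnitude response", {
  fs <- 30
  t <- seq(0, 10, by = 1 / fs)

  expect_equal(lowpass(rep(3, length(t)), fs), rep(3, length(t)),
               tolerance = 1e-9) # DC gain 1

  # squared order-4 magnitude response at f: 1 / (1 + (f/6)^8)
  resp2 <- function(f) 1 / (1 + (f / 6)^(2 * 4))
  amp_after <- function(f) {
    x <- sin(2 * pi * f * t)
    y <- lowpass(x, fs)
    core <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
    sqrt(mean(y[core]^2)) / sqrt(mean(x[core]^2))
  }
  expect_equal(amp_after(1), resp2(1), tolerance = 0.01) # passband: ~1
  expect_lt(amp_after(12), 0.01) # stopband: >99% attenuation

  expect_error(lowpass(t, fs, cutoff = 15), class = "gaitverify_domain_error")
  expect_error(lowpass(rep(1, 10), fs, order = 4),
               class = "gaitverify_domain_error")
})

test_that("filtering is nearly idempotent on band-limited gait signals", {
  m <- default_gait_model(1.0)
  t <- seq(0, 20, by = 1 / 30)
  x <- angle_at_phase(m, "knee", t / m$cycle_duration)
  y1 <- lowpass(x, 30)
  y2 <- lowpass(y1, 30)
  core <- seq(31, length(t) - 30)
  expect_lt(sqrt(mean((y2[core] - y1[core])^2)), 0.1)
})

test_that("flexion_angle matches hand-constructed geometry and symmetry", {
  # collinear: full extension
  expect_equal(flexion_angle(c(0, 0, 1), c(0, 0, 0), c(0, 0, -1)), 0,
               tolerance = 1e-12)

  # knee at origin, hip above, ankle 40 degrees forward of straight-down
  a40 <- 40 * pi / 180
  knee <- flexion_angle(c(0, 0, 1), c(0, 0, 0),
                        c(sin(a40), 0, -cos(a40)))
  expect_equal(knee, 40, tolerance = 1e-9)

  # reflecting through the sagittal plane flips the sign, keeps magnitude
  refl <- flexion_angle(c(0, 0, 1), c(0, 0, 0),
                        c(sin(a40), 0, -cos(a40)) * c(1, -1, 1),
                        sagittal_normal = c(0, -1, 0))
  expect_equal(abs(refl), 40, tolerance = 1e-9)

  expect_error(flexion_angle(c(0, 1e-15, 0), c(0, 0, 0), c(1, 0, 0)),
               class = "gaitverify_degenerate_error")
})

test_that("markerless chain recovers ground-truth angles on clean input", {
  trial <- small_trial(duration = 8)
  ang <- markerless_angles(trial$markerless, trial$extrinsics)
  core <- ang[ang$time_s > 0.5 & ang$time_s < max(ang$time_s) - 0.5, ]
  m <- trial$model
  for (j in c("hip", "knee")) {
    sub <- core[core$joint == j, ]
    truth <- angle_at_phase(m, j, sub$time_s / m$cycle_duration)
    expect_lt(sqrt(mean((sub$angle_deg - truth)^2)), 0.5)
  }
})

test_that("angles_from_skeleton enforces presence and handles standing", {
  trial <- small_trial(duration = 6)
  fused <- fuse_keypoints(to_world(trial$markerless, trial$extrinsics))

  gone <- fused
  gone$x_m[gone$keypoint == "right_ankle"] <- NA_real_
  expect_error(angles_from_skeleton(gone),
               class = "gaitverify_missingness_error")

  # constant standing pose: collinear trunk-thigh-shank, both angles 0
  flat <- gait_model(list(hip = list(a0 = 0, a = 0, b = 0),
                          knee = list(a0 = 0, a = 0, b = 0)),
                     cycle_duration = 1)
  poses <- pose_series(flat, anthropometry(), 3, rate = 30)
  skel <- poses
  skel$n_cameras <- 1
  attr(skel, "sample_rate") <- 30
  ang <- angles_from_skeleton(skel)
  expect_lt(max(abs(ang$angle_deg)), 1e-6)
})

test_that("angles are invariant under sagittal-preserving rigid transforms", {
  trial <- small_trial(duration = 6)
  world <- to_world(trial$markerless, trial$extrinsics)
  fused <- fuse_keypoints(world)
  base <- angles_from_skeleton(fused)

  # translation + rotation about the mediolateral (Y) axis preserves the
  # sagittal plane and hence both magnitude and sign
  th <- 0.4
  ry <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
               3, byrow = TRUE)
  moved <- fused
  p <- rbind(moved$x_m, moved$y_m, moved$z_m)
  q <- ry %*% p + c(0.5, -2, 1)
  moved$x_m <- q[1, ]; moved$y_m <- q[2, ]; moved$z_m <- q[3, ]
  attr(moved, "sample_rate") <- attr(fused, "sample_rate")
  rot <- angles_from_skeleton(moved)
  expect_equal(rot$angle_deg, base$angle_deg, tolerance = 1e-9)

  # unprojected 3D included angle: magnitude invariant under any rotation
  rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, byrow = TRUE)
  moved2 <- fused
  q2 <- rz %*% p
  moved2$x_m <- q2[1, ]; moved2$y_m <- q2[2, ]; moved2$z_m <- q2[3, ]
  attr(moved2, "sample_rate") <- attr(fused, "sample_rate")
  base3d <- angles_from_skeleton(fused, project = FALSE)
  rot3d <- angles_from_skeleton(moved2, project = FALSE)
  expect_equal(abs(rot3d$angle_deg), abs(base3d$angle_deg), tolerance = 1e-9)
})
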