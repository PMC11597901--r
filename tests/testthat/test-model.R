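test_that("default gait model has the canonical waveform anatomy", {
  m <- default_gait_model(1.0)
  phi <- seq(0, 1, length.out = 20000)[-20000]
  knee <- angle_at_phase(m, "knee", phi)

  # exactly two local maxima per cycle: stance and swing flexion peaks
  is_max <- knee > c(tail(knee, 1), head(knee, -1)) &
    knee > c(tail(knee, -1), knee[1])
  expect_equal(sum(is_max), 2)

  # swing peak dominates; ranges typical of adult gait
  expect_gt(max(knee), 45)
  expect_lt(max(knee), 65)
  hip <- angle_at_phase(m, "hip", phi)
  expect_gt(max(hip), 20)
  expect_lt(min(hip), 0)

  # knee global minimum anchored at phase 0 (cycle start)
  expect_lt(phi[which.min(knee)], 1e-3)
})

test_that("gait model construction is deterministic and speed-monotone", {
  m1 <- default_gait_model(1.0)
  m2 <- default_gait_model(1.0)
  expect_identical(m1$coefficients, m2$coefficients)

  expect_lt(default_gait_model(1.3)$cycle_duration,
            default_gait_model(0.7)$cycle_duration)
  expect_error(default_gait_model(0), class = "gaitverify_domain_error")
  expect_error(default_gait_model(-1), class = "gaitverify_domain_error")
})

test_that("angle_at_phase evaluates the Fourier series with wrapping", {
  m <- default_gait_model(1.0)
  expect_equal(angle_at_phase(m, "knee", 0), angle_at_phase(m, "knee", 1))
  expect_equal(angle_at_phase(m, "hip", 0.3), angle_at_phase(m, "hip", 2.3))

  flat <- gait_model(list(hip = list(a0 = 5, a = 0, b = 0),
                          knee = list(a0 = 5, a = 0, b = 0)),
                     cycle_duration = 1)
  expect_equal(angle_at_phase(flat, "hip", c(0, 0.2, 0.9)), rep(5, 3))

  one_h <- gait_model(list(hip = list(a0 = 0, a = 1, b = 0),
                           knee = list(a0 = 0, a = 1, b = 0)),
                      cycle_duration = 1)
  expect_equal(angle_at_phase(one_h, "knee", 0.5), -1) # cos(pi)

  expect_error(angle_at_phase(m, "ankle", 0), class = "gaitverify_domain_error")
})

test_that("skeleton pose is self-consistent with the vector angle method", {
  m <- default_gait_model(1.0)
  a <- anthropometry()
  phases <- c(0, 0.12, 0.3, 0.48, 0.66, 0.85)
  pose <- skeleton_pose(m, a, phases)

  for (i in seq_along(phases)) {
    sub <- pose[seq((i - 1) * 17 + 1, i * 17), ]
    g <- function(kp) unlist(sub[sub$keypoint == kp, c("x_m", "y_m", "z_m")])
    hip <- flexion_angle(g("right_shoulder"), g("right_hip"), g("right_knee"))
    knee <- flexion_angle(g("right_ankle"), g("right_knee"), g("right_hip"))
    expect_equal(hip, angle_at_phase(m, "hip", phases[i]), tolerance = 1e-6)
    expect_equal(knee, angle_at_phase(m, "knee", phases[i]), tolerance = 1e-6)
  }

  # left side mirrors with a half-cycle shift
  sub <- pose[1:17, ]
  g <- function(kp) unlist(sub[sub$keypoint == kp, c("x_m", "y_m", "z_m")])
  left_knee <- flexion_angle(g("left_ankle"), g("left_knee"), g("left_hip"))
  expect_equal(left_knee, angle_at_phase(m, "knee", 0.5), tolerance = 1e-6)
})

test_that("zero flexion gives collinear segments; scaling leaves angles", {
  flat <- gait_model(list(hip = list(a0 = 0, a = 0, b = 0),
                          knee = list(a0 = 0, a = 0, b = 0)),
                     cycle_duration = 1)
  a <- anthropometry()
  pose <- skeleton_pose(flat, a, 0.25)
  g <- function(kp) unlist(pose[pose$keypoint == kp, c("x_m", "y_m", "z_m")])
  hip <- g("right_hip"); knee <- g("right_knee"); ankle <- g("right_ankle")
  v1 <- (knee - hip) / sqrt(sum((knee - hip)^2))
  v2 <- (ankle - knee) / sqrt(sum((ankle - knee)^2))
  expect_lt(max(abs(v1 - v2)), 1e-9) # collinear chain

  # doubling stature: segment vectors scale, angles unchanged
  m <- default_gait_model(1.0)
  p1 <- skeleton_pose(m, anthropometry(stature = 1.75), 0.4)
  p2 <- skeleton_pose(m, anthropometry(stature = 3.50), 0.4)
  g1 <- function(kp) unlist(p1[p1$keypoint == kp, c("x_m", "y_m", "z_m")])
  g2 <- function(kp) unlist(p2[p2$keypoint == kp, c("x_m", "y_m", "z_m")])
  seg1 <- g1("right_knee") - g1("right_hip")
  seg2 <- g2("right_knee") - g2("right_hip")
  expect_equal(seg2, seg1 * 2, tolerance = 1e-12)
  k1 <- flexion_angle(g1("right_ankle"), g1("right_knee"), g1("right_hip"))
  k2 <- flexion_angle(g2("right_ankle"), g2("right_knee"), g2("right_hip"))
  expect_equal(k1, k2, tolerance = 1e-9)
})

test_that("perturbation preserves the knee-minimum anchor and ROM identity", {
  m <- default_gait_model(1.0)
  p <- perturb_gait_model(m, scale = c(hip = 1.2, knee = 0.85),
                          offset = c(hip = -3, knee = 4), cycle_scale = 1.05)
  phi <- seq(0, 1, length.out = 20000)[-20000]
  knee <- angle_at_phase(p, "knee", phi)
  expect_lt(phi[which.min(knee)], 1e-3)
  expect_equal(p$cycle_duration, m$cycle_duration * 1.05)

  tp <- true_discrete_params(p)
  expect_equal(tp$rom_deg, tp$max_deg - tp$min_deg)
  expect_error(perturb_gait_model(m, scale = c(hip = -1, knee = 1)),
               class = "gaitverify_domain_error")
})

test_that("anthropometry rejects impossible segment fractions", {
  expect_error(anthropometry(trunk_frac = 0.5, thigh_frac = 0.3,
                             shank_frac = 0.3),
               class = "gaitverify_domain_error")
  expect_error(anthropometry(stature = -1), class = "gaitverify_domain_error")
})
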