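test_that("knee-minimum events sit at the troughs of a known sinusoid", {
  t <- seq(0, 5, by = 1 / 30)
  wave <- tibble::tibble(time_s = t,
                         angle_deg = 30 + 25 * cos(2 * pi * t)) # troughs at 0.5, 1.5, ...
  ev <- detect_knee_min_events(wave, expected_cycle_s = 1)
  expect_gte(nrow(ev), 4)
  offs <- (ev$time_s - 0.5) %% 1
  offs <- pmin(offs, 1 - offs)
  expect_lt(max(offs), 1 / 30 + 1e-9) # within one sample
  expect_equal(diff(ev$time_s), rep(1, nrow(ev) - 1), tolerance = 1 / 30)

  # autocorrelation estimate of the period agrees
  ev2 <- detect_knee_min_events(wave)
  expect_equal(ev2$time_s, ev$time_s)
})

test_that("events recover ground-truth cycle starts on a clean trial", {
  trial <- small_trial(duration = 8)
  ang <- markerless_angles(trial$markerless, trial$extrinsics)
  core <- ang[ang$time_s > 0.5 & ang$time_s < max(ang$time_s) - 0.5, ]
  ev <- detect_knee_min_events(core)
  truth <- trial$cycle_starts
  err <- vapply(ev$time_s, function(e) min(abs(e - truth)), numeric(1))
  expect_lt(max(err), 1 / 30 + 1e-9) # within one 30 Hz sample

  flatwave <- tibble::tibble(time_s = seq(0, 5, by = 1 / 30), angle_deg = 7)
  expect_error(detect_knee_min_events(flatwave, expected_cycle_s = 1),
               class = "gaitverify_segmentation_error")
})

test_that("heel strikes are detected within 2 ms on synthetic force data", {
  m <- default_gait_model(1.0)
  grf <- synth_grf(m, 8)
  hs <- detect_heel_strikes(grf)
  truth <- seq(0, 8, by = m$cycle_duration)
  err <- vapply(hs$time_s, function(e) min(abs(e - truth)), numeric(1))
  expect_lt(max(err), 2e-3)

  zero <- tibble::tibble(time_s = seq(0, 1, by = 1e-3), fz_N = 0)
  expect_error(detect_heel_strikes(zero),
               class = "gaitverify_segmentation_error")
  expect_error(detect_heel_strikes(grf, threshold_N = 0),
               class = "gaitverify_domain_error")
})

test_that("segmentation and normalization resample cycles exactly", {
  t <- seq(0, 4, by = 0.01)
  const <- tibble::tibble(time_s = t, angle_deg = 7)
  ev <- tibble::tibble(time_s = c(0.5, 1.5, 2.5))
  cyc <- segment_and_normalize(const, ev, n = 101)
  expect_equal(unique(cyc$angle_deg), 7)
  expect_equal(nrow(cyc), 2 * 101)

  # a within-cycle linear ramp stays linear in phase
  ramp <- tibble::tibble(time_s = t, angle_deg = 3 * t)
  cyc2 <- segment_and_normalize(ramp, tibble::tibble(time_s = c(1, 2)), n = 51)
  expect_equal(cyc2$angle_deg, 3 * (1 + cyc2$phase_pct / 100),
               tolerance = 1e-9)

  # two identical cycles: pointwise SD is zero
  per <- tibble::tibble(time_s = t, angle_deg = sin(2 * pi * t))
  cyc3 <- segment_and_normalize(per, tibble::tibble(time_s = c(0, 1, 2)))
  expect_equal(max(cycle_mean(cyc3)$sd_deg), 0, tolerance = 1e-9)

  expect_error(segment_and_normalize(const, tibble::tibble(time_s = c(1, 9))),
               class = "gaitverify_validation_error")
})

test_that("normalization is idempotent on an existing phase grid", {
  one <- tibble::tibble(time_s = seq(0, 100, length.out = 101),
                        angle_deg = sin(seq(0, 2 * pi, length.out = 101)))
  cyc <- segment_and_normalize(one, tibble::tibble(time_s = c(0, 100)), n = 101)
  expect_equal(cyc$angle_deg, one$angle_deg, tolerance = 1e-12)
})

test_that("discrete parameters average per-cycle extrema", {
  cyc <- tibble::tibble(
    cycle = rep(1:2, each = 4),
    phase_pct = rep(c(0, 33, 66, 100), 2),
    angle_deg = c(0, 10, 0, -5, 0, 20, 0, -5)
  )
  p <- discrete_params(cyc)
  expect_equal(p$max_deg, 15) # (10 + 20) / 2
  expect_equal(p$min_deg, -5)
  expect_equal(p$rom_deg, p$max_deg - p$min_deg)

  single <- cyc[cyc$cycle == 1, ]
  p1 <- discrete_params(single)
  expect_equal(c(p1$max_deg, p1$min_deg, p1$rom_deg), c(10, -5, 15))

  pm <- discrete_params(cyc, average = "mean_curve")
  expect_equal(pm$max_deg, 15) # extrema of the mean curve here coincide
})

test_that("pipeline discrete parameters match ground truth on clean input", {
  trial <- small_trial(duration = 10)
  res <- process_trial(trial)
  truth <- trial$true_params
  for (j in c("hip", "knee")) {
    for (sys in c("mmc", "ref")) {
      row <- res[res$joint == j & res$system == sys, ]
      tr <- truth[truth$joint == j, ]
      expect_lt(abs(row$max_deg - tr$max_deg), 0.5)
      expect_lt(abs(row$min_deg - tr$min_deg), 0.5)
      expect_lt(abs(row$rom_deg - tr$rom_deg), 0.5)
    }
  }
})

test_that("30 Hz sampling underestimates averaged peaks relative to 100 Hz", {
  # peak undersampling: sampling a smooth peak at 30 Hz can only miss it
  m <- default_gait_model(1.0)
  set.seed(42)
  n_cycles <- 150
  max_at <- function(rate) {
    vapply(seq_len(n_cycles), function(i) {
      t0 <- runif(1) # random phase origin of the sampling grid
      t <- seq(t0, t0 + m$cycle_duration, by = 1 / rate)
      max(angle_at_phase(m, "knee", t / m$cycle_duration))
    }, numeric(1))
  }
  expect_lte(mean(max_at(30)), mean(max_at(100)))
})
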