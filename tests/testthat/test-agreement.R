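make_waves <- function(values_by_participant) {
  purrr::imap_dfr(values_by_participant, function(v, p) {
    tibble::tibble(participant = p, phase_pct = seq_along(v) - 1,
                   angle_deg = v)
  })
}

test_that("waveform RMSE summarises per-participant errors", {
  a <- make_waves(list(p1 = c(1, 2, 3), p2 = c(0, 0, 0)))
  expect_equal(rmse_waveforms(a, a)$mean, 0)
  expect_equal(rmse_waveforms(a, a)$sd, 0)

  b <- a
  b$angle_deg <- b$angle_deg + 3
  r <- rmse_waveforms(b, a)
  expect_equal(r$per_participant$rmse, c(3, 3))
  expect_equal(c(r$mean, r$sd), c(3, 0))

  h <- rmse_waveforms(make_waves(list(p = c(1, 2, 2))),
                      make_waves(list(p = c(0, 0, 0))))
  expect_equal(h$mean, sqrt(3)) # sqrt((1 + 4 + 4) / 3)

  bad <- a
  bad$phase_pct <- bad$phase_pct + 0.5
  expect_error(rmse_waveforms(a, bad), class = "gaitverify_validation_error")
})

test_that("Lin's CCC matches hand-computed values and bounds", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.4, 3.3, 2.8)
  expect_equal(lin_ccc(x, x)$lcc, 1)

  xc <- x - mean(x)
  expect_equal(lin_ccc(xc, -xc)$lcc, -1)

  # s_xy = 2, s_x^2 = 1, s_y^2 = 4, means 2 and 4 -> 4 / (5 + 4) = 4/9
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 4, 6))$lcc, 4 / 9, tolerance = 1e-12)

  expect_error(lin_ccc(rep(1, 5), rep(2, 5)),
               class = "gaitverify_degenerate_error")
  expect_error(lin_ccc(c(1, 2), c(1, 2)), class = "gaitverify_domain_error")
})

test_that("|CCC| never exceeds |r|, with equality iff moments match", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    x <- rnorm(n)
    y <- rnorm(n, sd = runif(1, 0.2, 3)) + runif(1, -2, 2) * x
    if (var(x) == 0 || var(y) == 0) next
    ccc <- lin_ccc(x, y)$lcc
    r <- cor(x, y)
    expect_lte(abs(ccc), abs(r) + 1e-12)
  }
  # equal means and variances: CCC equals r
  x <- rnorm(50)
  y <- x[sample(50)] # same marginal, permuted
  expect_equal(lin_ccc(x, y)$lcc, cor(x, y), tolerance = 1e-12)
})

test_that("Pearson correlation carries the interpretation bands", {
  x <- c(0.5, 1.5, 2.5, 4)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  expect_equal(gaitverify:::pearson_band(0.95), "very high")
  expect_equal(gaitverify:::pearson_band(-0.8), "high")
  expect_equal(gaitverify:::pearson_band(0.1), "negligible")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)),
               class = "gaitverify_degenerate_error")
})

test_that("Bland-Altman bias is the LoA midpoint with 2 z sd width", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))

  ba <- bland_altman(c(2, 4), c(1, 1)) # d = (1, 3)
  expect_equal(ba$bias, 2)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$loa_low, 2 - 1.96 * sqrt(2))
  expect_equal(ba$loa_high, 2 + 1.96 * sqrt(2))

  set.seed(9)
  a <- rnorm(20, 10, 3)
  b <- rnorm(20, 9, 2)
  bar <- bland_altman(a, b)
  expect_equal((bar$loa_low + bar$loa_high) / 2, bar$bias, tolerance = 1e-12)
  expect_equal(bar$loa_high - bar$loa_low, 2 * 1.96 * sd(a - b),
               tolerance = 1e-12)
})

test_that("ICC(2,1) matches the explicit ANOVA decomposition", {
  # brute-force oracle: mean squares from stats::aov
  icc_aov <- function(x) {
    n <- nrow(x); k <- ncol(x)
    d <- data.frame(y = as.vector(x), subj = factor(rep(seq_len(n), k)),
                    sess = factor(rep(seq_len(k), each = n)))
    ms <- summary(stats::aov(y ~ subj + sess, data = d))[[1]][["Mean Sq"]]
    (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + (k / n) * (ms[2] - ms[3]))
  }

  x <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), ncol = 2, byrow = TRUE)
  expect_equal(icc_2_1(x)$icc, icc_aov(x), tolerance = 1e-10)

  set.seed(11)
  for (i in 1:50) {
    n <- sample(3:6, 1)
    x <- matrix(rnorm(n * 2, 10, 3), ncol = 2)
    expect_equal(icc_2_1(x)$icc, icc_aov(x), tolerance = 1e-10)
  }
})

test_that("ICC(2,1) point and CI agree with an independent implementation", {
  # frozen oracle values from pingouin.intraclass_corr (ICC(A,1))
  x <- matrix(c(10.2, 11.0, 12.5, 12.1, 9.8, 10.5, 14.0, 13.2,
                11.1, 11.9, 13.3, 12.8, 10.9, 10.4, 12.0, 12.6),
              ncol = 2, byrow = TRUE)
  got <- icc_2_1(x)
  expect_equal(got$icc, 0.869829222011, tolerance = 1e-9)
  expect_equal(got$ci_low, 0.48, tolerance = 0.005)
  expect_equal(got$ci_high, 0.97, tolerance = 0.005)

  x2 <- matrix(c(
    20.0548587764, 23.0557988401, 17.2487984654, 16.4736326649,
    21.2924709866, 21.7391108583, 23.7001444505, 22.0079214209,
    14.0969685231, 14.7628738566, 15.9085991159, 17.2224337721,
    19.7025916651, 20.2695737518, 20.2738135616, 18.2111157460,
    19.7950670454, 19.1251153118, 17.0125403951, 18.0914610051,
    22.2860603741, 23.3814480958, 22.8656849918, 22.8765300746,
    20.5635361570, 19.5325823854, 23.7944562325, 23.6138849440,
    21.8333490298, 21.5192138359), ncol = 2, byrow = TRUE)
  got2 <- icc_2_1(x2)
  expect_equal(got2$icc, 0.900831592833, tolerance = 1e-9)
  expect_equal(got2$ci_low, 0.73, tolerance = 0.005)
  expect_equal(got2$ci_high, 0.97, tolerance = 0.005)
})

test_that("ICC degenerate and boundary structures behave as expected", {
  # identical sessions with between-participant spread: perfect reliability
  y <- c(3, 9, 15, 21, 30)
  expect_equal(icc_2_1(cbind(y, y))$icc, 1)

  # no between-participant variance, pure noise: ICC near zero
  set.seed(13)
  x <- matrix(rnorm(400), ncol = 2)
  expect_lte(icc_2_1(x)$icc, 0.1)

  expect_error(icc_2_1(matrix(5, 4, 2)),
               class = "gaitverify_degenerate_error")
  expect_error(icc_2_1(matrix(rnorm(4), 2, 2)),
               class = "gaitverify_domain_error")
})

test_that("SEM and MDC follow their defining arithmetic", {
  expect_equal(sem_from_icc(2, 1), 0)
  expect_equal(sem_from_icc(2, 0), 2)
  expect_equal(sem_from_icc(2, 0.75), 1)
  expect_error(sem_from_icc(2, 1.2), class = "gaitverify_domain_error")

  expect_equal(mdc_from_sem(0), 0)
  expect_equal(mdc_from_sem(1.60, "ratio"), 1.96 / sqrt(2) * 1.60)
  expect_equal(mdc_from_sem(1, "conventional"), 1.96 * sqrt(2),
               tolerance = 1e-4) # 2.7719
  # the two conventions differ by exactly a factor of 2
  expect_equal(mdc_from_sem(1.3, "conventional") / mdc_from_sem(1.3, "ratio"),
               2)
})

test_that("offset correction zeroes the mean residual and preserves ROM", {
  ref <- sin(seq(0, 2 * pi, length.out = 101)) * 20
  mmc <- ref + 6
  oc <- offset_correct(mmc, ref)
  expect_equal(oc$offset, 6)
  expect_equal(oc$corrected, ref)
  expect_lt(abs(mean(oc$corrected - ref)), 1e-12)

  set.seed(17)
  noisy <- ref + rnorm(101, 3, 1)
  oc2 <- offset_correct(noisy, ref)
  expect_lt(abs(mean(oc2$corrected - ref)), 1e-12)
  expect_equal(max(oc2$corrected) - min(oc2$corrected),
               max(noisy) - min(noisy), tolerance = 1e-12)

  expect_error(offset_correct(1:5, 1:4), class = "gaitverify_validation_error")
})
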