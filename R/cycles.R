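#' Detect gait-cycle starts from minimum knee flexion
#'
#' Finds the local minima of the knee flexion waveform (the markerless
#' segmentation event): candidate minima are ranked by depth and accepted
#' greedily subject to a minimum separation of
#' `min_separation_factor * expected_cycle_s`. When `expected_cycle_s` is not
#' supplied it is estimated from the waveform's autocorrelation.
#'
#' @param knee Tibble `time_s, angle_deg` (a single joint's waveform), or the
#'   long output of [angles_from_skeleton()] (the `knee` rows are used).
#' @param expected_cycle_s Expected cycle duration in seconds, or `NULL` to
#'   estimate by autocorrelation.
#' @param min_separation_factor Fraction of the expected cycle below which
#'   two minima cannot coexist (default 0.6).
#' @return A tibble `time_s, source` (`source = "knee_min"`), strictly
#'   increasing, with at least 2 events.
#' @export
detect_knee_min_events <- function(knee, expected_cycle_s = NULL,
                                   min_separation_factor = 0.6) {
  if ("joint" %in% names(knee)) {
    knee <- knee[knee$joint == "knee", ]
  }
  check_cols(knee, c("time_s", "angle_deg"), "knee waveform")
  t <- knee$time_s
  v <- knee$angle_deg
  check_no_na(v, "angle_deg")
  if (diff(range(v)) < 1e-9) {
    stop_gv("Knee waveform is constant; no cycles can be segmented.",
            class = "gaitverify_segmentation_error")
  }
  rate <- infer_rate(t, what = "knee waveform")

  if (is.null(expected_cycle_s)) {
    expected_cycle_s <- estimate_cycle_duration(v, rate)
  }
  check_number(expected_cycle_s, "expected_cycle_s", lower = 1e-9)
  if (max(t) - min(t) < 2 * expected_cycle_s) {
    stop_gv("Waveform must cover at least two expected cycles.",
            class = "gaitverify_segmentation_error")
  }

  n <- length(v)
  is_min <- c(FALSE, v[2:(n - 1)] < v[1:(n - 2)] & v[2:(n - 1)] <= v[3:n],
              FALSE)
  cand <- which(is_min)
  if (length(cand) < 2L) {
    stop_gv("Fewer than 2 knee-flexion minima found.",
            class = "gaitverify_segmentation_error")
  }
  # deepest-first greedy selection under the separation constraint
  sep <- min_separation_factor * expected_cycle_s
  cand <- cand[order(v[cand])]
  keep <- integer(0)
  for (i in cand) {
    if (all(abs(t[i] - t[keep]) >= sep)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  if (length(keep) < 2L) {
    stop_gv("Fewer than 2 separated knee-flexion minima found.",
            class = "gaitverify_segmentation_error")
  }
  tibble(time_s = t[keep], source = "knee_min")
}

# Cycle duration from the autocorrelation of a (detrended) periodic waveform.
# Integer-lag quantization can make a multiple of the period score slightly
# above the fundamental (the true period rarely is a whole number of
# samples), so among the local acf maxima past the first negative dip the
# SMALLEST lag within 80% of the best peak is taken, not the argmax.
estimate_cycle_duration <- function(v, rate) {
  v <- v - mean(v)
  n <- length(v)
  max_lag <- floor(n / 2)
  ac <- stats::acf(v, lag.max = max_lag, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  below <- which(ac < 0)
  if (length(below) == 0L) {
    stop_gv("Cannot estimate cycle duration: autocorrelation never dips.",
            class = "gaitverify_segmentation_error")
  }
  idx <- seq.int(below[1], length(ac))
  seg <- ac[idx]
  k <- length(seg)
  if (k < 3L) {
    stop_gv("Waveform too short to estimate a cycle duration.",
            class = "gaitverify_segmentation_error")
  }
  is_peak <- c(FALSE, seg[2:(k - 1)] > seg[1:(k - 2)] &
                 seg[2:(k - 1)] >= seg[3:k], FALSE)
  peaks <- idx[is_peak]
  if (length(peaks) == 0L) peaks <- idx[which.max(seg)]
  strong <- peaks[ac[peaks] >= 0.8 * max(ac[peaks])]
  lag <- min(strong) - 1L
  lag / rate
}

#' Detect heel strikes from vertical ground reaction force
#'
#' Upward crossings of a force threshold, with sub-sample timing by linear
#' interpolation and a refractory period that suppresses re-triggering within
#' the same stance phase.
#'
#' @param grf Tibble `time_s, fz_N` (e.g. from [synth_grf()] or
#'   [read_grf_table()]), sampled at 100 Hz or more.
#' @param threshold_N Detection threshold in newtons (> 0, default 20).
#' @param refractory_s Minimum time between events in seconds (default 0.3).
#' @return A tibble `time_s, source` (`source = "heel_strike"`).
#' @export
detect_heel_strikes <- function(grf, threshold_N = 20, refractory_s = 0.3) {
  check_cols(grf, c("time_s", "fz_N"), "grf")
  check_number(threshold_N, "threshold_N", lower = 1e-12)
  rate <- attr(grf, "sample_rate") %||% infer_rate(grf$time_s, what = "GRF")
  if (rate < 100) {
    stop_gv(sprintf("GRF rate %g Hz is below the required 100 Hz.", rate),
            class = "gaitverify_domain_error")
  }
  f <- grf$fz_N
  t <- grf$time_s
  up <- which(f[-1] >= threshold_N & f[-length(f)] < threshold_N)
  if (length(up) == 0L) {
    stop_gv("No threshold crossings found in the GRF series.",
            class = "gaitverify_segmentation_error")
  }
  # sub-sample crossing times
  tc <- t[up] + (threshold_N - f[up]) / (f[up + 1] - f[up]) * (t[up + 1] - t[up])
  keep <- tc[1]
  for (x in tc[-1]) {
    if (x - keep[length(keep)] >= refractory_s) keep <- c(keep, x)
  }
  tibble(time_s = keep, source = "heel_strike")
}

#' Segment a waveform into time-normalized gait cycles
#'
#' Each interval between consecutive events is linearly resampled to `n`
#' points spanning 0--100% of the gait cycle; data before the first and
#' after the last event are discarded.
#'
#' @param wave Tibble `time_s, angle_deg` (single-joint waveform).
#' @param events Event tibble from [detect_knee_min_events()] or
#'   [detect_heel_strikes()] (or any tibble with `time_s`).
#' @param n Number of phase samples (default 101, i.e. 0, 1, ..., 100%).
#' @return A `"cycle_set"` tibble `cycle, phase_pct, angle_deg` with
#'   `n` rows per cycle.
#' @export
segment_and_normalize <- function(wave, events, n = 101L) {
  if ("joint" %in% names(wave) && length(unique(wave$joint)) > 1L) {
    stop_gv("`wave` holds several joints; filter to one before segmenting.",
            class = "gaitverify_domain_error")
  }
  check_cols(wave, c("time_s", "angle_deg"), "wave")
  check_cols(events, "time_s", "events")
  check_number(n, "n", lower = 2)
  n <- as.integer(n)
  ev <- sort(events$time_s)
  if (length(ev) < 2L) {
    stop_gv("At least 2 events are needed to define a cycle.",
            class = "gaitverify_segmentation_error")
  }
  step <- median(diff(wave$time_s))
  lo <- min(wave$time_s) - step / 2
  hi <- max(wave$time_s) + step / 2
  if (any(ev < lo | ev > hi)) {
    stop_gv("Event time(s) outside the waveform support.",
            class = "gaitverify_validation_error")
  }
  phase <- seq(0, 100, length.out = n)
  out <- purrr::map_dfr(seq_len(length(ev) - 1L), function(k) {
    tt <- ev[k] + (ev[k + 1] - ev[k]) * phase / 100
    tibble(cycle = k, phase_pct = phase,
           angle_deg = approx(wave$time_s, wave$angle_deg, tt, rule = 2)$y)
  })
  class(out) <- c("cycle_set", class(out))
  attr(out, "normalized_points") <- n
  out
}

#' Pointwise mean and SD across normalized cycles
#'
#' @param cycles A `"cycle_set"` from [segment_and_normalize()].
#' @return A tibble `phase_pct, mean_deg, sd_deg, n_cycles`.
#' @export
cycle_mean <- function(cycles) {
  check_cols(cycles, c("cycle", "phase_pct", "angle_deg"), "cycles")
  cycles %>%
    dplyr::group_by(.data$phase_pct) %>%
    dplyr::summarise(mean_deg = mean(.data$angle_deg),
                     sd_deg = if (dplyr::n() > 1) sd(.data$angle_deg) else 0,
                     n_cycles = dplyr::n(),
                     .groups = "drop")
}

#' Discrete gait parameters from normalized cycles
#'
#' Computes the per-cycle maximum, minimum and range of motion, then averages
#' across cycles (average-of-extrema). `average = "mean_curve"` instead takes
#' the extrema of the pointwise mean waveform.
#'
#' @param cycles A `"cycle_set"` from [segment_and_normalize()].
#' @param average `"per_cycle"` (default) or `"mean_curve"`.
#' @return A one-row tibble `max_deg, min_deg, rom_deg, n_cycles` with
#'   `rom_deg = max_deg - min_deg` exactly.
#' @export
discrete_params <- function(cycles, average = c("per_cycle", "mean_curve")) {
  average <- match.arg(average)
  check_cols(cycles, c("cycle", "phase_pct", "angle_deg"), "cycles")
  if (nrow(cycles) == 0L) {
    stop_gv("Empty cycle set.", class = "gaitverify_domain_error")
  }
  if (average == "per_cycle") {
    per <- cycles %>%
      dplyr::group_by(.data$cycle) %>%
      dplyr::summarise(mx = max(.data$angle_deg), mn = min(.data$angle_deg),
                       .groups = "drop")
    mx <- mean(per$mx)
    mn <- mean(per$mn)
    k <- nrow(per)
  } else {
    m <- cycle_mean(cycles)
    mx <- max(m$mean_deg)
    mn <- min(m$mean_deg)
    k <- length(unique(cycles$cycle))
  }
  tibble(max_deg = mx, min_deg = mn, rom_deg = mx - mn, n_cycles = k)
}
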