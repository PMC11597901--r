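#' Process one trial through both measurement chains
#'
#' Markerless chain: camera streams to world frame, fusion, filtering, vector
#' angles, knee-minimum segmentation, 0-100% normalization. Reference chain:
#' reference angle stream segmented at force-plate heel strikes and
#' normalized on the same grid. Discrete parameters are per-cycle extrema
#' averaged across cycles.
#'
#' @param trial A `"gait_trial"` (see [generate_study()]), or any list with
#'   `markerless`, `extrinsics`, `reference`, `grf` and metadata fields.
#' @param cfg A [stats_config()].
#' @param trim_s Seconds trimmed from each end of the markerless angle
#'   waveforms before segmentation, discarding zero-phase filter edge
#'   transients (default 0.5).
#' @return A tibble with one row per system x joint: `participant, session,
#'   speed, system, joint, max_deg, min_deg, rom_deg, n_cycles`, plus a
#'   `mean_wave` list column (numeric vector on the phase grid).
#' @export
process_trial <- function(trial, cfg = stats_config(), trim_s = 0.5) {
  n_pts <- cfg$normalized_points

  # --- markerless chain ---
  mmc_angles <- markerless_angles(trial$markerless, trial$extrinsics, cfg)
  t_rng <- range(mmc_angles$time_s)
  mmc_angles <- mmc_angles[mmc_angles$time_s >= t_rng[1] + trim_s &
                             mmc_angles$time_s <= t_rng[2] - trim_s, ]
  knee_events <- detect_knee_min_events(mmc_angles)

  # --- reference chain ---
  hs_events <- detect_heel_strikes(trial$grf)
  ref <- trial$reference

  per_system <- list(
    mmc = list(angles = mmc_angles, events = knee_events),
    ref = list(angles = ref, events = hs_events)
  )
  purrr::imap_dfr(per_system, function(sys, sys_name) {
    purrr::map_dfr(c("hip", "knee"), function(j) {
      wave <- sys$angles[sys$angles$joint == j, ]
      ev <- sys$events
      # events must lie inside this waveform's support
      ev <- ev[ev$time_s >= min(wave$time_s) & ev$time_s <= max(wave$time_s), ]
      cycles <- segment_and_normalize(wave, ev, n = n_pts)
      pars <- discrete_params(cycles)
      tibble(participant = trial$participant,
             session = trial$session,
             speed = trial$speed,
             system = sys_name,
             joint = j,
             max_deg = pars$max_deg,
             min_deg = pars$min_deg,
             rom_deg = pars$rom_deg,
             n_cycles = pars$n_cycles,
             mean_wave = list(cycle_mean(cycles)$mean_deg))
    })
  })
}

#' Process every trial of a study
#'
#' @param study Tibble from [generate_study()] (columns `participant`,
#'   `session`, `speed`, `trial`).
#' @param cfg A [stats_config()].
#' @param ... Passed to [process_trial()].
#' @return Row-bound [process_trial()] results for all trials.
#' @export
analyze_study <- function(study, cfg = stats_config(), ...) {
  check_cols(study, c("participant", "session", "speed", "trial"), "study")
  purrr::map_dfr(study$trial, process_trial, cfg = cfg, ...)
}

# long (participant, phase_pct, angle_deg) table from a mean_wave list column
waves_long <- function(df) {
  n <- length(df$mean_wave[[1]])
  phase <- seq(0, 100, length.out = n)
  purrr::map_dfr(seq_len(nrow(df)), function(i) {
    tibble(participant = df$participant[i],
           phase_pct = phase,
           angle_deg = df$mean_wave[[i]])
  })
}

#' Test-retest reliability report
#'
#' For each joint and speed: ICC(2,1) with its confidence interval, SEM and
#' MDC for the averaged maximum, minimum and ROM between sessions 1 and 2
#' (SD pooled over both sessions' measurements), plus waveform agreement
#' between the per-participant session mean waveforms: RMSE (mean and SD
#' across participants) and Lin's CCC pooled over all participants' waveform
#' samples.
#'
#' @param results Output of [analyze_study()]; only `system == "mmc"` rows
#'   are used.
#' @param cfg A [stats_config()].
#' @return A `"reliability_report"` object with tibbles `params` and
#'   `waveforms`.
#' @export
reliability_report <- function(results, cfg = stats_config()) {
  res <- results[results$system == "mmc", ]
  if (!all(c(1, 2) %in% unique(res$session))) {
    stop_gv("Reliability needs sessions 1 and 2 in the results.",
            class = "gaitverify_validation_error")
  }
  combos <- dplyr::distinct(res, .data$joint, .data$speed)

  params <- purrr::pmap_dfr(combos, function(joint, speed) {
    sub <- res[res$joint == joint & res$speed == speed, ]
    s1 <- sub[sub$session == 1, ]
    s2 <- sub[sub$session == 2, ]
    if (!setequal(s1$participant, s2$participant)) {
      stop_gv("Participants differ between sessions.",
              class = "gaitverify_validation_error")
    }
    s2 <- s2[match(s1$participant, s2$participant), ]
    purrr::map_dfr(c(max = "max_deg", min = "min_deg", rom = "rom_deg"),
                   function(col) {
      x <- cbind(s1[[col]], s2[[col]])
      ic <- icc_2_1(x)
      sem <- sem_from_icc(sd(as.vector(x)), ic$icc)
      tibble(icc = ic$icc, icc_ci_low = ic$ci_low, icc_ci_high = ic$ci_high,
             icc_interpretation = ic$interpretation,
             sem = sem,
             mdc = mdc_from_sem(sem, convention = cfg$mdc_convention,
                                z = cfg$z_coverage))
    }, .id = "measure") %>%
      mutate(joint = joint, speed = speed, .before = 1)
  })

  waveforms <- purrr::pmap_dfr(combos, function(joint, speed) {
    sub <- res[res$joint == joint & res$speed == speed, ]
    w1 <- waves_long(sub[sub$session == 1, ])
    w2 <- waves_long(sub[sub$session == 2, ])
    rm <- rmse_waveforms(w1, w2)
    paired <- dplyr::inner_join(w1, w2, by = c("participant", "phase_pct"),
                                suffix = c("_1", "_2"))
    lc <- lin_ccc(paired$angle_deg_1, paired$angle_deg_2)
    tibble(joint = joint, speed = speed,
           rmse_mean = rm$mean, rmse_sd = rm$sd,
           lcc = lc$lcc, lcc_ci_low = lc$ci_low, lcc_ci_high = lc$ci_high,
           lcc_interpretation = lc$interpretation)
  })

  structure(list(params = params, waveforms = waveforms, cfg = cfg),
            class = "reliability_report")
}

#' Accuracy report: markerless vs reference system
#'
#' For each joint and speed: Bland-Altman bias with limits of agreement and
#' Pearson's r for the averaged maximum, minimum and ROM (markerless minus
#' reference), plus waveform RMSE (mean, SD across participants) and pooled
#' Lin's CCC. With `corrected = TRUE` the constant offset (mean waveform
#' difference, per participant and session) is removed from the markerless
#' stream before all statistics; maxima and minima shift by the offset while
#' ROM is untouched.
#'
#' @param results Output of [analyze_study()] (both systems present).
#' @param corrected Apply per-participant offset correction first?
#' @param cfg A [stats_config()].
#' @param session Session(s) to include (default 1).
#' @return An `"accuracy_report"` object with tibbles `params` and
#'   `waveforms` and the `corrected` flag.
#' @export
accuracy_report <- function(results, corrected = FALSE, cfg = stats_config(),
                            session = 1) {
  res <- results[results$session %in% session, ]
  key <- c("participant", "session", "speed", "joint")
  mmc <- res[res$system == "mmc", ]
  ref <- res[res$system == "ref", ]
  pairs <- dplyr::inner_join(mmc, ref, by = key, suffix = c("_mmc", "_ref"))
  if (nrow(pairs) != nrow(mmc) || nrow(pairs) != nrow(ref)) {
    stop_gv("Trial pairing failed: unmatched markerless/reference rows.",
            class = "gaitverify_validation_error")
  }

  # per participant-session offset from the mean waveforms (hip and knee
  # separately), applied as a constant shift to waveform and extrema
  pairs$offset <- purrr::map2_dbl(pairs$mean_wave_mmc, pairs$mean_wave_ref,
                                  function(m, r) offset_correct(m, r)$offset)
  if (corrected) {
    pairs$mean_wave_mmc <- purrr::map2(pairs$mean_wave_mmc, pairs$offset,
                                       function(w, o) w - o)
    pairs$max_deg_mmc <- pairs$max_deg_mmc - pairs$offset
    pairs$min_deg_mmc <- pairs$min_deg_mmc - pairs$offset
    # rom_deg is shift-invariant and deliberately left untouched
  }

  combos <- dplyr::distinct(pairs, .data$joint, .data$speed)
  params <- purrr::pmap_dfr(combos, function(joint, speed) {
    sub <- pairs[pairs$joint == joint & pairs$speed == speed, ]
    purrr::map_dfr(c(max = "max_deg", min = "min_deg", rom = "rom_deg"),
                   function(col) {
      a <- sub[[paste0(col, "_mmc")]]
      b <- sub[[paste0(col, "_ref")]]
      ba <- bland_altman(a, b, z = cfg$z_coverage)
      pr <- tryCatch(pearson_r(a, b),
                     gaitverify_degenerate_error = function(e)
                       tibble(r = NA_real_, n = length(a),
                              interpretation = NA_character_))
      tibble(bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
             r = pr$r, r_interpretation = pr$interpretation, n = ba$n)
    }, .id = "measure") %>%
      mutate(joint = joint, speed = speed, .before = 1)
  })

  waveforms <- purrr::pmap_dfr(combos, function(joint, speed) {
    sub <- pairs[pairs$joint == joint & pairs$speed == speed, ]
    n_pts <- length(sub$mean_wave_mmc[[1]])
    phase <- seq(0, 100, length.out = n_pts)
    wm <- purrr::map_dfr(seq_len(nrow(sub)), function(i)
      tibble(participant = sub$participant[i], phase_pct = phase,
             angle_deg = sub$mean_wave_mmc[[i]]))
    wr <- purrr::map_dfr(seq_len(nrow(sub)), function(i)
      tibble(participant = sub$participant[i], phase_pct = phase,
             angle_deg = sub$mean_wave_ref[[i]]))
    rm <- rmse_waveforms(wm, wr)
    lc <- lin_ccc(wm$angle_deg, wr$angle_deg)
    tibble(joint = joint, speed = speed,
           rmse_mean = rm$mean, rmse_sd = rm$sd,
           lcc = lc$lcc, lcc_ci_low = lc$ci_low, lcc_ci_high = lc$ci_high,
           lcc_interpretation = lc$interpretation)
  })

  structure(list(params = params, waveforms = waveforms,
                 corrected = corrected, cfg = cfg),
            class = "accuracy_report")
}

#' Run a complete synthetic validation study
#'
#' Generates a synthetic study, runs every trial through both measurement
#' chains, and produces the three publication-style tables: test-retest
#' reliability, accuracy against the reference, and accuracy after offset
#' correction. Deterministic for a fixed seed.
#'
#' @param n_participants,sessions,speeds,obs_model,seed,duration Passed to
#'   [generate_study()].
#' @param cfg A [stats_config()].
#' @param out_dir Optional directory; when given, the three tables are
#'   written as CSVs and a machine-readable JSON of every statistic is
#'   saved (requires the jsonlite package).
#' @param ... Further arguments for [generate_study()].
#' @return A `"validation_study"` object: `reliability`,
#'   `accuracy_uncorrected`, `accuracy_corrected`, the per-trial `results`
#'   tibble, `seed` and `cfg`.
#' @export
run_validation_study <- function(n_participants = 15, sessions = 2,
                                 speeds = c(0.7, 1.0, 1.3),
                                 obs_model = observation_model(),
                                 seed = 1, duration = 60,
                                 cfg = stats_config(), out_dir = NULL, ...) {
  study <- generate_study(n_participants = n_participants, sessions = sessions,
                          speeds = speeds, obs_model = obs_model, seed = seed,
                          duration = duration, ...)
  results <- analyze_study(study, cfg = cfg)
  rel <- reliability_report(results, cfg = cfg)
  acc_u <- accuracy_report(results, corrected = FALSE, cfg = cfg)
  acc_c <- accuracy_report(results, corrected = TRUE, cfg = cfg)

  out <- structure(list(reliability = rel,
                        accuracy_uncorrected = acc_u,
                        accuracy_corrected = acc_c,
                        results = results,
                        seed = seed, cfg = cfg),
                   class = "validation_study")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(render_table(rel, "csv"),
                     file.path(out_dir, "reliability.csv"))
    readr::write_csv(render_table(acc_u, "csv"),
                     file.path(out_dir, "accuracy_uncorrected.csv"))
    readr::write_csv(render_table(acc_c, "csv"),
                     file.path(out_dir, "accuracy_corrected.csv"))
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      stats_list <- list(
        seed = seed,
        reliability = list(params = rel$params, waveforms = rel$waveforms),
        accuracy_uncorrected = list(params = acc_u$params,
                                    waveforms = acc_u$waveforms),
        accuracy_corrected = list(params = acc_c$params,
                                  waveforms = acc_c$waveforms))
      jsonlite::write_json(stats_list, file.path(out_dir, "statistics.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  out
}

#' @export
print.validation_study <- function(x, ...) {
  cat(sprintf("<validation_study> seed %s\n", format(x$seed)))
  cat("\n-- Test-retest reliability --\n")
  print(render_table(x$reliability), n = Inf)
  cat("\n-- Accuracy vs reference (uncorrected) --\n")
  print(render_table(x$accuracy_uncorrected), n = Inf)
  cat("\n-- Accuracy vs reference (offset corrected) --\n")
  print(render_table(x$accuracy_corrected), n = Inf)
  invisible(x)
}

# "x.xx (lo hi)" with 2-decimal round-half-even formatting; missing cells
# render as an em dash
fmt_val <- function(x, lo = NULL, hi = NULL) {
  f <- function(v) {
    out <- formatC(round(v, 2), format = "f", digits = 2)
    if (anyNA(v)) {
      warn("Missing cell(s) rendered as —.")
      out[is.na(v)] <- "—"
    }
    out
  }
  if (is.null(lo)) f(x) else sprintf("%s (%s %s)", f(x), f(lo), f(hi))
}

#' Render a report as a publication-style table
#'
#' Lays out a reliability or accuracy report in the wide per-joint-per-speed
#' format used in validation papers, with `"value (low high)"` strings and
#' 2-decimal round-half-even rounding. `style = "csv"` returns the same
#' numbers as plain numeric columns.
#'
#' @param report A `"reliability_report"` or `"accuracy_report"`.
#' @param style `"text"` (formatted strings, default) or `"csv"` (numeric).
#' @return A tibble, one row per joint x speed.
#' @export
render_table <- function(report, style = c("text", "csv")) {
  style <- match.arg(style)
  if (inherits(report, "reliability_report")) {
    wide <- report$params %>%
      tidyr::pivot_wider(
        id_cols = c("joint", "speed"), names_from = "measure",
        values_from = c("icc", "icc_ci_low", "icc_ci_high", "sem", "mdc"))
    tbl <- dplyr::left_join(wide, report$waveforms, by = c("joint", "speed"))
    if (style == "csv") return(tbl)
    tibble(
      joint = tbl$joint, speed = tbl$speed,
      icc_max = fmt_val(tbl$icc_max, tbl$icc_ci_low_max, tbl$icc_ci_high_max),
      sem_max = fmt_val(tbl$sem_max), mdc_max = fmt_val(tbl$mdc_max),
      icc_min = fmt_val(tbl$icc_min, tbl$icc_ci_low_min, tbl$icc_ci_high_min),
      sem_min = fmt_val(tbl$sem_min), mdc_min = fmt_val(tbl$mdc_min),
      icc_rom = fmt_val(tbl$icc_rom, tbl$icc_ci_low_rom, tbl$icc_ci_high_rom),
      sem_rom = fmt_val(tbl$sem_rom), mdc_rom = fmt_val(tbl$mdc_rom),
      rmse = fmt_val(tbl$rmse_mean) %>%
        paste0(" (", fmt_val(tbl$rmse_sd), ")"),
      lcc = fmt_val(tbl$lcc, tbl$lcc_ci_low, tbl$lcc_ci_high)
    )
  } else if (inherits(report, "accuracy_report")) {
    wide <- report$params %>%
      tidyr::pivot_wider(
        id_cols = c("joint", "speed"), names_from = "measure",
        values_from = c("bias", "loa_low", "loa_high", "r"))
    tbl <- dplyr::left_join(wide, report$waveforms, by = c("joint", "speed"))
    if (style == "csv") return(tbl)
    tibble(
      joint = tbl$joint, speed = tbl$speed,
      bias_max = fmt_val(tbl$bias_max, tbl$loa_low_max, tbl$loa_high_max),
      r_max = fmt_val(tbl$r_max),
      bias_min = fmt_val(tbl$bias_min, tbl$loa_low_min, tbl$loa_high_min),
      r_min = fmt_val(tbl$r_min),
      bias_rom = fmt_val(tbl$bias_rom, tbl$loa_low_rom, tbl$loa_high_rom),
      r_rom = fmt_val(tbl$r_rom),
      rmse = fmt_val(tbl$rmse_mean) %>%
        paste0(" (", fmt_val(tbl$rmse_sd), ")"),
      lcc = fmt_val(tbl$lcc, tbl$lcc_ci_low, tbl$lcc_ci_high)
    )
  } else {
    stop_gv("`report` must be a reliability_report or accuracy_report.",
            class = "gaitverify_domain_error")
  }
}
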