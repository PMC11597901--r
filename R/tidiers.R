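#' Tidy a reliability report
#'
#' @param x A `"reliability_report"`.
#' @param ... Unused.
#' @return The per-measure statistics as a long tibble (one row per joint x
#'   speed x measure) joined with the waveform statistics.
#' @export
tidy.reliability_report <- function(x, ...) {
  dplyr::left_join(x$params, x$waveforms, by = c("joint", "speed"))
}

#' @rdname tidy.reliability_report
#' @export
tidy.accuracy_report <- function(x, ...) {
  out <- dplyr::left_join(x$params, x$waveforms, by = c("joint", "speed"))
  out$corrected <- x$corrected
  out
}

#' @rdname tidy.reliability_report
#' @export
tidy.validation_study <- function(x, ...) {
  dplyr::bind_rows(
    reliability = dplyr::select(tidy(x$reliability), "joint", "speed",
                                "measure", value = "icc"),
    accuracy_uncorrected = dplyr::select(tidy(x$accuracy_uncorrected),
                                         "joint", "speed", "measure",
                                         value = "bias"),
    accuracy_corrected = dplyr::select(tidy(x$accuracy_corrected),
                                       "joint", "speed", "measure",
                                       value = "bias"),
    .id = "table"
  )
}

#' One-row summaries of validation reports
#'
#' @param x A `"reliability_report"`, `"accuracy_report"` or
#'   `"validation_study"`.
#' @param ... Unused.
#' @return A one-row tibble with the headline quantities: worst-case MDC and
#'   waveform RMSE and the weakest ICC/LCC (reliability), or the largest
#'   absolute bias and mean RMSE (accuracy).
#' @export
glance.reliability_report <- function(x, ...) {
  tibble(min_icc = min(x$params$icc),
         max_sem = max(x$params$sem),
         max_mdc = max(x$params$mdc),
         max_rmse = max(x$waveforms$rmse_mean),
         min_lcc = min(x$waveforms$lcc))
}

#' @rdname glance.reliability_report
#' @export
glance.accuracy_report <- function(x, ...) {
  tibble(corrected = x$corrected,
         max_abs_bias = max(abs(x$params$bias)),
         mean_rmse = mean(x$waveforms$rmse_mean),
         max_rmse = max(x$waveforms$rmse_mean),
         min_lcc = min(x$waveforms$lcc))
}

#' @rdname glance.reliability_report
#' @export
glance.validation_study <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$reliability),
    dplyr::rename_with(glance(x$accuracy_corrected),
                       function(nm) paste0("corrected_", nm))
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("<reliability_report> (test-retest, sessions 1 vs 2)\n")
  print(render_table(x), n = Inf)
  invisible(x)
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> markerless vs reference%s\n",
              if (x$corrected) ", offset corrected" else ""))
  print(render_table(x), n = Inf)
  invisible(x)
}

#' Plot normalized gait cycles
#'
#' Mean waveform with a pointwise mean +/- SD ribbon over the 0--100% gait
#' phase, with the individual cycles in the background.
#'
#' @param object A `"cycle_set"` from [segment_and_normalize()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cycle_set <- function(object, ...) {
  m <- cycle_mean(object)
  ggplot(m, aes(x = .data$phase_pct)) +
    geom_line(data = object,
              aes(y = .data$angle_deg, group = .data$cycle),
              colour = "grey70", linewidth = 0.3) +
    geom_ribbon(aes(ymin = .data$mean_deg - .data$sd_deg,
                    ymax = .data$mean_deg + .data$sd_deg),
                alpha = 0.3, fill = "steelblue") +
    geom_line(aes(y = .data$mean_deg), colour = "steelblue", linewidth = 1) +
    labs(x = "Gait cycle [%]", y = "Flexion angle [deg]") +
    theme_minimal()
}

#' Plot the two systems' mean waveforms for a validation study
#'
#' Mean +/- SD ribbons (across participants) of the markerless and reference
#' waveforms per joint, at one speed, session 1.
#'
#' @param object A `"validation_study"` from [run_validation_study()].
#' @param speed Speed to display (default: first speed present).
#' @param corrected Show offset-corrected markerless waveforms?
#' @param ... Unused.
#' @return A ggplot object faceted by joint.
#' @export
autoplot.validation_study <- function(object, speed = NULL, corrected = FALSE,
                                      ...) {
  res <- object$results[object$results$session == 1, ]
  speed <- speed %||% min(res$speed)
  res <- res[res$speed == speed, ]
  n <- length(res$mean_wave[[1]])
  phase <- seq(0, 100, length.out = n)

  df <- purrr::map_dfr(seq_len(nrow(res)), function(i) {
    w <- res$mean_wave[[i]]
    tibble(system = res$system[i], joint = res$joint[i],
           participant = res$participant[i], phase_pct = phase, angle_deg = w)
  })
  if (corrected) {
    # subtract per participant-joint the mean difference to the reference
    df <- df %>%
      tidyr::pivot_wider(names_from = "system", values_from = "angle_deg") %>%
      dplyr::group_by(.data$joint, .data$participant) %>%
      mutate(mmc = .data$mmc - mean(.data$mmc - .data$ref)) %>%
      ungroup() %>%
      tidyr::pivot_longer(c("mmc", "ref"), names_to = "system",
                          values_to = "angle_deg")
  }
  summ <- df %>%
    dplyr::group_by(.data$system, .data$joint, .data$phase_pct) %>%
    dplyr::summarise(m = mean(.data$angle_deg), s = sd(.data$angle_deg),
                     .groups = "drop")
  ggplot(summ, aes(x = .data$phase_pct, colour = .data$system,
                   fill = .data$system)) +
    geom_ribbon(aes(ymin = .data$m - .data$s, ymax = .data$m + .data$s),
                alpha = 0.25, colour = NA) +
    geom_line(aes(y = .data$m), linewidth = 0.9) +
    facet_wrap(~joint, scales = "free_y") +
    labs(x = "Gait cycle [%]", y = "Flexion angle [deg]",
         title = sprintf("Mean +/- SD waveforms at %.1f m/s%s", speed,
                         if (corrected) " (offset corrected)" else "")) +
    theme_minimal()
}

#' Bland-Altman plot for one discrete parameter
#'
#' @param results Output of [analyze_study()].
#' @param joint,speed,measure Cell to display (`measure` one of `"max"`,
#'   `"min"`, `"rom"`).
#' @param z Coverage quantile for the limits of agreement.
#' @param session Session to use (default 1).
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(results, joint, speed, measure = "rom",
                              z = 1.96, session = 1) {
  col <- paste0(measure, "_deg")
  res <- results[results$joint == joint & results$speed == speed &
                   results$session %in% session, ]
  wide <- res %>%
    dplyr::select("participant", "system", dplyr::all_of(col)) %>%
    tidyr::pivot_wider(names_from = "system", values_from = dplyr::all_of(col))
  ba <- bland_altman(wide$mmc, wide$ref, z = z)
  df <- tibble(mean_val = (wide$mmc + wide$ref) / 2,
               diff_val = wide$mmc - wide$ref)
  ggplot(df, aes(x = .data$mean_val, y = .data$diff_val)) +
    geom_point() +
    geom_hline(yintercept = ba$bias, colour = "red") +
    geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
               colour = "darkgreen", linetype = "dashed") +
    labs(x = sprintf("Mean of systems [%s %s, deg]", joint, measure),
         y = "Markerless - reference [deg]",
         title = sprintf("Bland-Altman: %s %s at %.1f m/s", joint, measure,
                         speed)) +
    theme_minimal()
}
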