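# Interpretation bands for correlation-type statistics, as used in the
# motion-capture validation literature.

pearson_band <- function(r) {
  a <- abs(r)
  dplyr::case_when(a < 0.30 ~ "negligible",
                   a < 0.50 ~ "low",
                   a < 0.70 ~ "moderate",
                   a < 0.90 ~ "high",
                   TRUE ~ "very high")
}

lcc_band <- function(ccc) {
  dplyr::case_when(ccc < 0.90 ~ "poor",
                   ccc < 0.95 ~ "moderate",
                   ccc < 0.99 ~ "substantial",
                   TRUE ~ "almost perfect")
}

icc_band <- function(icc) {
  dplyr::case_when(icc < 0.5 ~ "poor",
                   icc < 0.75 ~ "moderate",
                   icc < 0.9 ~ "good",
                   TRUE ~ "excellent")
}

#' Per-participant waveform RMSE between two systems
#'
#' Computes the root-mean-square error over the normalized phase grid for
#' each participant's pair of mean waveforms, then the mean and standard
#' deviation of those RMSEs across participants.
#'
#' @param a,b Long tibbles `participant, phase_pct, angle_deg` holding each
#'   participant's mean waveform for system A and system B on a common grid.
#' @return A list with `per_participant` (tibble `participant, rmse`),
#'   `mean` and `sd`.
#' @export
rmse_waveforms <- function(a, b) {
  check_cols(a, c("participant", "phase_pct", "angle_deg"), "a")
  check_cols(b, c("participant", "phase_pct", "angle_deg"), "b")
  joined <- dplyr::inner_join(a, b, by = c("participant", "phase_pct"),
                              suffix = c("_a", "_b"))
  if (nrow(joined) != nrow(a) || nrow(joined) != nrow(b)) {
    stop_gv("Waveform grids/participants do not match between systems.",
            class = "gaitverify_validation_error")
  }
  per <- joined %>%
    dplyr::group_by(.data$participant) %>%
    dplyr::summarise(
      rmse = sqrt(mean((.data$angle_deg_a - .data$angle_deg_b)^2)),
      .groups = "drop")
  list(per_participant = per,
       mean = mean(per$rmse),
       sd = if (nrow(per) > 1) sd(per$rmse) else 0)
}

#' Lin's concordance correlation coefficient
#'
#' `lcc = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with n-1
#' denominators, penalizing both dispersion and location shifts. The
#' confidence interval uses the Fisher z-transform with Lin's asymptotic
#' standard error. At `|lcc| = 1` the standard error degenerates and the CI
#' collapses to the point estimate.
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble `lcc, ci_low, ci_high, n, interpretation`.
#' @export
lin_ccc <- function(x, y, conf_level = 0.95) {
  check_no_na(x, "x")
  check_no_na(y, "y")
  n <- length(x)
  if (length(y) != n) {
    stop_gv("`x` and `y` must have equal length.",
            class = "gaitverify_validation_error")
  }
  if (n < 3L) {
    stop_gv("Lin's CCC needs at least 3 pairs.",
            class = "gaitverify_domain_error")
  }
  sx2 <- var(x)
  sy2 <- var(y)
  if (sx2 == 0 && sy2 == 0) {
    stop_gv("Lin's CCC is undefined when both variances are zero.",
            class = "gaitverify_degenerate_error")
  }
  sxy <- stats::cov(x, y)
  dmu <- mean(x) - mean(y)
  ccc <- 2 * sxy / (sx2 + sy2 + dmu^2)

  if (sx2 == 0 || sy2 == 0) {
    # correlation undefined: no asymptotic CI available
    return(tibble(lcc = ccc, ci_low = NA_real_, ci_high = NA_real_, n = n,
                  interpretation = lcc_band(ccc)))
  }
  r <- sxy / sqrt(sx2 * sy2)
  u <- dmu / (sx2 * sy2)^0.25
  if (1 - ccc^2 < 1e-12 || abs(r) < 1e-12) {
    ci <- c(ccc, ccc)
  } else {
    se_z <- sqrt(((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
                    4 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
                    2 * ccc^4 * u^4 / (r^2 * (1 - ccc^2)^2)) / (n - 2))
    zq <- qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(atanh(ccc) + c(-1, 1) * zq * se_z)
  }
  tibble(lcc = ccc, ci_low = ci[1], ci_high = ci[2], n = n,
         interpretation = lcc_band(ccc))
}

#' Pearson correlation with interpretation band
#'
#' @param x,y Paired numeric vectors (n >= 3), both with nonzero variance.
#' @return A one-row tibble `r, n, interpretation` (bands: <0.30 negligible,
#'   0.30-0.50 low, 0.50-0.70 moderate, 0.70-0.90 high, 0.90-1.00 very high).
#' @export
pearson_r <- function(x, y) {
  check_no_na(x, "x")
  check_no_na(y, "y")
  if (length(x) != length(y)) {
    stop_gv("`x` and `y` must have equal length.",
            class = "gaitverify_validation_error")
  }
  if (length(x) < 3L) {
    stop_gv("Pearson correlation needs at least 3 pairs.",
            class = "gaitverify_domain_error")
  }
  if (var(x) == 0 || var(y) == 0) {
    stop_gv("Pearson correlation is undefined for zero-variance input.",
            class = "gaitverify_degenerate_error")
  }
  r <- cor(x, y)
  tibble(r = r, n = length(x), interpretation = pearson_band(r))
}

#' Bland-Altman analysis
#'
#' Differences are `a - b`; the bias is their mean and the limits of
#' agreement are `bias +/- z * sd(differences)` (n-1 standard deviation), so
#' the bias is always the midpoint of the limits.
#'
#' @param a,b Paired numeric vectors (system A, system B).
#' @param z Normal coverage quantile (default 1.96).
#' @return A one-row tibble `bias, loa_low, loa_high, sd_diff, n`.
#' @export
bland_altman <- function(a, b, z = 1.96) {
  check_no_na(a, "a")
  check_no_na(b, "b")
  if (length(a) != length(b)) {
    stop_gv("`a` and `b` must have equal length.",
            class = "gaitverify_validation_error")
  }
  d <- a - b
  s <- if (length(d) > 1) sd(d) else 0
  bias <- mean(d)
  tibble(bias = bias, loa_low = bias - z * s, loa_high = bias + z * s,
         sd_diff = s, n = length(d))
}

#' ICC(2,1): two-way random effects, absolute agreement, single measures
#'
#' Computes the intraclass correlation from the two-way ANOVA decomposition
#' (subjects x sessions):
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`,
#' with the F-based confidence interval of McGraw & Wong (1996).
#'
#' @param data Either an `n x k` numeric matrix (rows = subjects, columns =
#'   sessions/raters) or a data frame with columns `participant`, `session`,
#'   `value`.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble
#'   `icc, ci_low, ci_high, n, k, interpretation` (bands: <0.5 poor,
#'   0.5-0.75 moderate, 0.75-0.9 good, >=0.9 excellent).
#' @export
icc_2_1 <- function(data, conf_level = 0.95) {
  if (is.data.frame(data) && !is.matrix(data)) {
    check_cols(data, c("participant", "session", "value"), "data")
    wide <- tidyr::pivot_wider(data[, c("participant", "session", "value")],
                               names_from = "session", values_from = "value")
    data <- as.matrix(wide[, -1, drop = FALSE])
  }
  x <- as.matrix(data)
  if (anyNA(x)) {
    stop_gv("ICC input must be complete (no NA).",
            class = "gaitverify_validation_error")
  }
  n <- nrow(x)
  k <- ncol(x)
  if (n < 3L || k < 2L) {
    stop_gv("ICC(2,1) needs at least 3 subjects and 2 sessions.",
            class = "gaitverify_domain_error")
  }
  grand <- mean(x)
  if (sum((x - grand)^2) < 1e-24) {
    stop_gv("ICC is undefined: total variance is zero.",
            class = "gaitverify_degenerate_error")
  }
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((x - grand)^2) - k * sum((row_m - grand)^2) -
    n * sum((col_m - grand)^2)
  mse <- sse / ((n - 1) * (k - 1))

  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  # McGraw & Wong F-based interval for ICC(A,1)
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  # qf can emit a qbeta-accuracy warning at the extreme Satterthwaite df
  # that arise for near-degenerate inputs; the bound is still usable
  f_l <- suppressWarnings(qf(1 - alpha / 2, df1 = n - 1, df2 = v))
  f_u <- suppressWarnings(qf(1 - alpha / 2, df1 = v, df2 = n - 1))
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)

  tibble(icc = icc, ci_low = lower, ci_high = upper, n = n, k = k,
         interpretation = icc_band(icc))
}

#' Standard error of measurement from a reliability coefficient
#'
#' `SEM = sd * sqrt(1 - ICC)`, with `sd` pooled over all measurements of
#' both sessions.
#'
#' @param sd_pooled Pooled standard deviation of the measurements (>= 0).
#' @param icc Reliability coefficient (<= 1; negative estimates are accepted
#'   and yield SEM > sd).
#' @return SEM, same units as `sd_pooled`.
#' @export
sem_from_icc <- function(sd_pooled, icc) {
  check_number(sd_pooled, "sd_pooled", lower = 0)
  if (icc > 1) {
    stop_gv("`icc` cannot exceed 1.", class = "gaitverify_domain_error")
  }
  sd_pooled * sqrt(1 - icc)
}

#' Minimal detectable change from SEM
#'
#' Two factor conventions are provided: `"ratio"` uses
#' `MDC = z * SEM / sqrt(2)` (~1.386 SEM at 95% coverage), the arithmetic
#' that published gait-reliability tables mirrored by this package satisfy
#' cell by cell; `"conventional"` uses the textbook
#' `MDC95 = z * sqrt(2) * SEM` (~2.772 SEM).
#'
#' @param sem Standard error of measurement (>= 0).
#' @param convention `"ratio"` (default) or `"conventional"`.
#' @param z Normal coverage quantile (default 1.96).
#' @return MDC, same units as `sem`.
#' @export
mdc_from_sem <- function(sem, convention = c("ratio", "conventional"),
                         z = 1.96) {
  check_number(sem, "sem", lower = 0)
  convention <- match.arg(convention)
  factor <- switch(convention, ratio = z / sqrt(2), conventional = z * sqrt(2))
  factor * sem
}

#' Remove the constant waveform offset between two systems
#'
#' Subtracts the mean over the phase grid of `(mmc - ref)` from the
#' markerless waveform, the standard correction for a constant joint-center
#' localization offset. By construction the corrected residual has exactly
#' zero mean, and any shift-invariant statistic (ROM in particular) is
#' unchanged.
#'
#' @param mmc,ref Numeric vectors on a common phase grid (markerless and
#'   reference mean waveforms).
#' @return A list with `corrected` (numeric vector) and `offset` (scalar,
#'   degrees).
#' @export
offset_correct <- function(mmc, ref) {
  check_no_na(mmc, "mmc")
  check_no_na(ref, "ref")
  if (length(mmc) != length(ref)) {
    stop_gv("`mmc` and `ref` must share a common phase grid.",
            class = "gaitverify_validation_error")
  }
  offset <- mean(mmc - ref)
  list(corrected = mmc - offset, offset = offset)
}
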