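#' The COCO-17 keypoint schema
#'
#' Names of the 17 body keypoints produced by COCO-trained pose estimators,
#' in canonical order. The foot is represented by the ankle alone, so ankle
#' kinematics are out of reach of this schema; hip and knee flexion are the
#' angles this package computes.
#'
#' @return A character vector of length 17.
#' @export
#' @examples
#' coco17_keypoints()
coco17_keypoints <- function() {
  c("nose",
    "left_eye", "right_eye",
    "left_ear", "right_ear",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle")
}

#' Analysis configuration
#'
#' Bundles the numeric conventions used across the pipeline: normal coverage
#' for limits of agreement and MDC, the MDC factor convention, the length of
#' the normalized gait-phase grid, and the Butterworth filter design applied
#' to keypoint trajectories.
#'
#' @param z_coverage Normal quantile for limits of agreement / MDC coverage
#'   (default 1.96, i.e. 95%).
#' @param mdc_convention Either `"ratio"` (MDC = 1.96 * SEM / sqrt(2), the
#'   convention reproduced by published reliability tables this package
#'   mirrors) or `"conventional"` (MDC95 = 1.96 * sqrt(2) * SEM).
#' @param normalized_points Samples on the 0--100% gait-phase grid
#'   (default 101, the field convention).
#' @param filter_order Butterworth order before zero-phase application
#'   (default 4).
#' @param filter_cutoff Low-pass cutoff in Hz applied to raw keypoint
#'   trajectories (default 6).
#' @return A list with class `"stats_config"`.
#' @export
#' @examples
#' stats_config()
stats_config <- function(z_coverage = 1.96,
                         mdc_convention = c("ratio", "conventional"),
                         normalized_points = 101L,
                         filter_order = 4L,
                         filter_cutoff = 6) {
  check_number(z_coverage, "z_coverage", lower = 1e-12)
  mdc_convention <- match.arg(mdc_convention)
  check_number(normalized_points, "normalized_points", lower = 2)
  check_number(filter_order, "filter_order", lower = 1)
  check_number(filter_cutoff, "filter_cutoff", lower = 1e-12)
  structure(
    list(z_coverage = z_coverage,
         mdc_convention = mdc_convention,
         normalized_points = as.integer(normalized_points),
         filter_order = as.integer(filter_order),
         filter_cutoff = filter_cutoff),
    class = "stats_config")
}

#' @export
print.stats_config <- function(x, ...) {
  cat("<stats_config>\n")
  cat(sprintf("  z coverage:        %.3f\n", x$z_coverage))
  cat(sprintf("  MDC convention:    %s\n", x$mdc_convention))
  cat(sprintf("  normalized points: %d\n", x$normalized_points))
  cat(sprintf("  filter:            Butterworth order %d, cutoff %g Hz\n",
              x$filter_order, x$filter_cutoff))
  invisible(x)
}

# MDC multiplier under the configured convention.
mdc_factor <- function(cfg) {
  switch(cfg$mdc_convention,
         ratio = cfg$z_coverage / sqrt(2),
         conventional = cfg$z_coverage * sqrt(2))
}

# Validate a long keypoint tibble (one camera or many). Enforces the COCO-17
# schema, confidence range, finite coordinates where present, and per-camera
# monotone time.
validate_keypoint_tbl <- function(df, what = "keypoint table") {
  check_cols(df, c("camera", "frame", "time_s", "keypoint",
                   "x_m", "y_m", "z_m", "confidence"), what)
  bad <- setdiff(unique(df$keypoint), coco17_keypoints())
  if (length(bad) > 0L) {
    stop_gv(sprintf("%s contains unknown keypoint name(s): %s.",
                    what, paste(bad, collapse = ", ")),
            class = "gaitverify_validation_error")
  }
  if (any(!is.na(df$confidence) & (df$confidence < 0 | df$confidence > 1))) {
    stop_gv(sprintf("%s has confidence values outside [0, 1].", what),
            class = "gaitverify_validation_error")
  }
  if (any(is.nan(df$x_m) | is.nan(df$y_m) | is.nan(df$z_m))) {
    stop_gv(sprintf(
      "%s has NaN coordinates; encode missing detections as NA.", what),
      class = "gaitverify_validation_error")
  }
  for (cam in unique(df$camera)) {
    sub <- df[df$camera == cam, c("frame", "time_s")]
    sub <- dplyr::distinct(dplyr::arrange(sub, .data$frame))
    if (anyDuplicated(sub$frame) || is.unsorted(sub$time_s, strictly = TRUE)) {
      stop_gv(sprintf(
        "%s: time is not strictly increasing with frame in camera '%s'.",
        what, cam),
        class = "gaitverify_validation_error")
    }
  }
  invisible(df)
}
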