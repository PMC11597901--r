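#' Bundled summary tables from a published validation study
#'
#' Summary statistics transcribed from a published treadmill validation study
#' of a multi-camera markerless gait-analysis system against marker-based
#' motion capture (15 healthy adults, two sessions, speeds 0.7/1.0/1.3 m/s,
#' right hip and knee flexion/extension). These printed values serve as
#' inputs for arithmetic consistency checks: the MDC-to-SEM factor of the
#' reliability table and the bias-equals-LoA-midpoint identity of the
#' Bland-Altman cells.
#'
#' @param which One of `"reliability_params"` (ICC/SEM/MDC per joint x speed
#'   x measure), `"reliability_waveforms"` (waveform RMSE and LCC),
#'   `"accuracy_uncorrected"` or `"accuracy_corrected"` (Bland-Altman bias,
#'   limits of agreement and Pearson r per joint x speed x measure).
#' @return A tibble.
#' @export
#' @examples
#' reference_table("accuracy_corrected")
reference_table <- function(which = c("reliability_params",
                                      "reliability_waveforms",
                                      "accuracy_uncorrected",
                                      "accuracy_corrected")) {
  which <- match.arg(which)
  path <- system.file("extdata", "reference_tables",
                      paste0(which, ".csv"), package = "gaitverify",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
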