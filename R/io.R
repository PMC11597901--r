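#' Read a multi-camera 3D keypoint table
#'
#' Reads a delimited text file of per-frame 3D keypoint detections in the
#' long layout `camera,frame,time_s,keypoint,x_m,y_m,z_m,confidence`
#' (one row per camera x frame x keypoint). Missing detections are encoded
#' as empty/NA coordinates, never as zeros. Keypoint names must belong to
#' the COCO-17 schema (see [coco17_keypoints()]).
#'
#' @param path Path to a CSV file.
#' @param ref_frame Frame of reference the coordinates are expressed in:
#'   `"camera"` (default, as produced by depth cameras) or `"world"`.
#' @return A tibble sorted by camera and time, with the input columns plus
#'   `ref_frame`.
#' @seealso [write_keypoint_table()], [to_world()]
#' @export
read_keypoint_table <- function(path, ref_frame = c("camera", "world")) {
  ref_frame <- match.arg(ref_frame)
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      camera = readr::col_character(),
      frame = readr::col_integer(),
      time_s = readr::col_double(),
      keypoint = readr::col_character(),
      x_m = readr::col_double(),
      y_m = readr::col_double(),
      z_m = readr::col_double(),
      confidence = readr::col_double()
    ),
    progress = FALSE
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    stop_gv(sprintf("Malformed keypoint table '%s': first problem at line %d (%s).",
                    path, probs$row[1], probs$expected[1]),
            class = "gaitverify_parse_error")
  }
  df <- dplyr::arrange(df, .data$camera, .data$time_s, .data$keypoint)
  df$ref_frame <- ref_frame
  validate_keypoint_tbl(df, sprintf("keypoint table '%s'", path))
  df
}

#' Write a keypoint table to CSV
#'
#' Inverse of [read_keypoint_table()]; coordinates are written with enough
#' precision to round-trip to at least 6 decimals.
#'
#' @param df Keypoint tibble (long layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_keypoint_table <- function(df, path) {
  check_cols(df, c("camera", "frame", "time_s", "keypoint",
                   "x_m", "y_m", "z_m", "confidence"), "keypoint table")
  out <- df[, c("camera", "frame", "time_s", "keypoint",
                "x_m", "y_m", "z_m", "confidence")]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read marker trajectories from a TRC file
#'
#' Parses the standard tab-delimited TRC motion-capture format (header rows
#' `DataRate ... Units`, marker-name row, X/Y/Z component row, then data).
#' Millimetre units are converted to metres.
#'
#' @param path Path to a `.trc` file.
#' @return A long tibble `frame, time_s, marker, x_m, y_m, z_m` with
#'   attribute `sample_rate` (Hz) taken from the header `DataRate`.
#' @export
read_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) {
    stop_gv(sprintf("TRC file '%s' is too short to contain a header.", path),
            class = "gaitverify_validation_error")
  }
  hdr_names <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  hdr_vals <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  hdr <- setNames(as.list(hdr_vals), hdr_names)
  need <- c("DataRate", "NumFrames", "NumMarkers", "Units")
  if (!all(need %in% names(hdr))) {
    stop_gv(sprintf("TRC header of '%s' lacks %s.", path,
                    paste(setdiff(need, names(hdr)), collapse = ", ")),
            class = "gaitverify_validation_error")
  }
  rate <- as.numeric(hdr$DataRate)
  n_frames <- as.integer(hdr$NumFrames)
  n_markers <- as.integer(hdr$NumMarkers)
  units <- hdr$Units
  scale <- switch(units, mm = 1e-3, m = 1,
                  stop_gv(sprintf("TRC units '%s' not supported.", units),
                          class = "gaitverify_validation_error"))

  marker_row <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  markers <- marker_row[-(1:2)]
  markers <- markers[markers != ""]
  if (length(markers) != n_markers) {
    stop_gv(sprintf(
      "TRC '%s': header NumMarkers=%d but %d marker names found.",
      path, n_markers, length(markers)),
      class = "gaitverify_validation_error")
  }

  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) != n_frames) {
    stop_gv(sprintf("TRC '%s': header NumFrames=%d but %d data rows found.",
                    path, n_frames, length(data_lines)),
            class = "gaitverify_validation_error")
  }
  mat <- do.call(rbind, lapply(data_lines, function(l) {
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])
  }))
  if (ncol(mat) != 2 + 3 * n_markers) {
    stop_gv(sprintf("TRC '%s': expected %d columns per data row, got %d.",
                    path, 2 + 3 * n_markers, ncol(mat)),
            class = "gaitverify_validation_error")
  }

  out <- purrr::map_dfr(seq_len(n_markers), function(i) {
    tibble(
      frame = as.integer(mat[, 1]),
      time_s = mat[, 2],
      marker = markers[i],
      x_m = mat[, 2 + 3 * (i - 1) + 1] * scale,
      y_m = mat[, 2 + 3 * (i - 1) + 2] * scale,
      z_m = mat[, 2 + 3 * (i - 1) + 3] * scale
    )
  })
  attr(out, "sample_rate") <- rate
  out
}

#' Write marker trajectories to a TRC file
#'
#' @param df Long tibble `frame, time_s, marker, x_m, y_m, z_m`.
#' @param path Output path.
#' @param rate Sampling rate in Hz (default: `sample_rate` attribute of `df`).
#' @param units `"mm"` (default, standard for TRC) or `"m"`.
#' @return `path`, invisibly.
#' @export
write_trc <- function(df, path, rate = attr(df, "sample_rate"), units = "mm") {
  check_cols(df, c("frame", "time_s", "marker", "x_m", "y_m", "z_m"), "TRC data")
  if (is.null(rate)) stop_gv("`rate` is required (no sample_rate attribute).")
  scale <- switch(units, mm = 1e3, m = 1,
                  stop_gv("`units` must be 'mm' or 'm'."))
  markers <- unique(df$marker)
  frames <- sort(unique(df$frame))
  times <- df$time_s[match(frames, df$frame)]
  wide <- matrix(NA_real_, nrow = length(frames), ncol = 3 * length(markers))
  for (i in seq_along(markers)) {
    sub <- df[df$marker == markers[i], ]
    idx <- match(sub$frame, frames)
    wide[idx, 3 * (i - 1) + 1] <- sub$x_m * scale
    wide[idx, 3 * (i - 1) + 2] <- sub$y_m * scale
    wide[idx, 3 * (i - 1) + 3] <- sub$z_m * scale
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste(c("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                     "Units", "OrigDataRate", "OrigDataStartFrame",
                     "OrigNumFrames"), collapse = "\t"), con)
  writeLines(paste(c(format(rate), format(rate), length(frames),
                     length(markers), units, format(rate), "1",
                     length(frames)), collapse = "\t"), con)
  writeLines(paste(c("Frame#", "Time",
                     as.vector(rbind(markers, "", ""))), collapse = "\t"), con)
  comp <- as.vector(vapply(seq_along(markers), function(i)
    paste0(c("X", "Y", "Z"), i), character(3)))
  writeLines(paste(c("", "", comp), collapse = "\t"), con)
  writeLines("", con)
  for (r in seq_along(frames)) {
    writeLines(paste(c(frames[r], format(times[r], digits = 12),
                       format(wide[r, ], digits = 12)), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a vertical ground-reaction-force series
#'
#' Reads a two-column CSV `time_s,fz_N` and validates that forces are
#' non-negative and sampling is uniform.
#'
#' @param path Path to a CSV file.
#' @param tol Relative tolerance on sample spacing irregularity.
#' @return A tibble `time_s, fz_N` with attribute `sample_rate` (Hz).
#' @export
read_grf_table <- function(path, tol = 1e-3) {
  df <- readr::read_csv(path,
                        col_types = readr::cols(time_s = readr::col_double(),
                                                fz_N = readr::col_double()),
                        progress = FALSE)
  if (nrow(df) == 0L) {
    stop_gv(sprintf("GRF file '%s' contains no rows.", path),
            class = "gaitverify_validation_error")
  }
  check_no_na(df$fz_N, "fz_N")
  if (any(df$fz_N < 0)) {
    stop_gv(sprintf("GRF file '%s' contains negative forces.", path),
            class = "gaitverify_validation_error")
  }
  attr(df, "sample_rate") <- infer_rate(df$time_s, tol = tol,
                                        what = sprintf("GRF '%s'", path))
  df
}

#' Write a vertical ground-reaction-force series to CSV
#'
#' @param df Tibble `time_s, fz_N`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grf_table <- function(df, path) {
  check_cols(df, c("time_s", "fz_N"), "GRF table")
  readr::write_csv(df[, c("time_s", "fz_N")], path, progress = FALSE)
  invisible(path)
}

#' Camera extrinsics table
#'
#' Constructs (or validates) a table of camera-to-world rigid transforms:
#' one row per camera with the rotation in row-major order (`r11 ... r33`)
#' and the translation in metres (`tx, ty, tz`). World points are obtained
#' as `p_world = R %*% p_cam + t`.
#'
#' @param camera Character vector of camera ids.
#' @param rotation List of 3x3 orthonormal matrices (det +1), one per camera.
#' @param translation List of length-3 numeric vectors, one per camera.
#' @return A tibble `camera, r11..r33, tx, ty, tz`.
#' @export
extrinsics_table <- function(camera, rotation, translation) {
  stopifnot(length(camera) == length(rotation),
            length(camera) == length(translation))
  rows <- purrr::map_dfr(seq_along(camera), function(i) {
    R <- rotation[[i]]
    check_rotation(R, camera[i])
    t <- translation[[i]]
    if (length(t) != 3L || anyNA(t)) {
      stop_gv(sprintf("Translation for camera '%s' must be 3 finite numbers.",
                      camera[i]),
              class = "gaitverify_validation_error")
    }
    tibble(camera = camera[i],
           r11 = R[1, 1], r12 = R[1, 2], r13 = R[1, 3],
           r21 = R[2, 1], r22 = R[2, 2], r23 = R[2, 3],
           r31 = R[3, 1], r32 = R[3, 2], r33 = R[3, 3],
           tx = t[1], ty = t[2], tz = t[3])
  })
  rows
}

#' @rdname extrinsics_table
#' @param path CSV path with the `extrinsics_table()` columns.
#' @export
read_extrinsics <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    camera = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  check_cols(df, c("camera", paste0("r", outer(1:3, 1:3, paste0)),
                   "tx", "ty", "tz"), "extrinsics table")
  for (i in seq_len(nrow(df))) {
    check_rotation(extrinsics_rotation(df[i, ]), df$camera[i])
  }
  df
}

#' @rdname extrinsics_table
#' @param df Extrinsics tibble.
#' @export
write_extrinsics <- function(df, path) {
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

# Rotation matrix / translation vector for a single extrinsics row.
extrinsics_rotation <- function(row) {
  matrix(c(row$r11, row$r12, row$r13,
           row$r21, row$r22, row$r23,
           row$r31, row$r32, row$r33), nrow = 3, byrow = TRUE)
}

extrinsics_translation <- function(row) {
  c(row$tx, row$ty, row$tz)
}
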