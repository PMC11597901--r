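# Internal validation helpers. All user-facing errors go through rlang::abort
# with a class so callers can condition on them.

stop_gv <- function(msg, class = "gaitverify_error", ...) {
  rlang::abort(msg, class = c(class, "gaitverify_error"), ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L) {
    stop_gv(sprintf("`%s` must be a single number.", name),
            class = "gaitverify_domain_error")
  }
  if (!allow_na && !is.finite(x)) {
    stop_gv(sprintf("`%s` must be finite.", name),
            class = "gaitverify_domain_error")
  }
  if (x < lower || x > upper) {
    stop_gv(sprintf("`%s` must be in [%s, %s], got %s.",
                    name, format(lower), format(upper), format(x)),
            class = "gaitverify_domain_error")
  }
  invisible(x)
}

check_no_na <- function(x, name) {
  if (anyNA(x)) {
    stop_gv(sprintf("`%s` must not contain NA/NaN.", name),
            class = "gaitverify_validation_error")
  }
  invisible(x)
}

check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_gv(sprintf("%s is missing column(s): %s.",
                    what, paste(missing, collapse = ", ")),
            class = "gaitverify_validation_error")
  }
  invisible(df)
}

# Uniform sample rate inferred from a timestamp vector; errors if spacing is
# irregular beyond `tol` (relative to the median step).
infer_rate <- function(time_s, tol = 1e-3, what = "series") {
  if (length(time_s) < 2L) {
    stop_gv(sprintf("%s needs at least 2 samples to infer a rate.", what),
            class = "gaitverify_validation_error")
  }
  dt <- diff(time_s)
  step <- median(dt)
  if (step <= 0 || any(abs(dt - step) > tol * step)) {
    stop_gv(sprintf("%s is not uniformly sampled.", what),
            class = "gaitverify_validation_error")
  }
  1 / step
}

# Orthonormality check for a camera-to-world rotation.
check_rotation <- function(R, camera_id = "?") {
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L)) || anyNA(R)) {
    stop_gv(sprintf("Rotation for camera '%s' must be a 3x3 numeric matrix.",
                    camera_id),
            class = "gaitverify_validation_error")
  }
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8) {
    stop_gv(sprintf(
      "Rotation for camera '%s' is not orthonormal with determinant +1.",
      camera_id),
      class = "gaitverify_validation_error")
  }
  invisible(R)
}
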