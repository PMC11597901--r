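#' Periodic gait waveform model
#'
#' A gait model describes hip and knee flexion/extension as truncated Fourier
#' series in gait phase \eqn{\phi \in [0, 1)}, together with the cycle
#' duration and the stance fraction. Phase 0 is the cycle start, defined as
#' the instant of minimum knee flexion (which coincides with heel strike in
#' this model, so knee-minimum segmentation and force-plate segmentation
#' agree on synthetic data).
#'
#' @param coefficients Named list (`hip`, `knee`), each a list with numeric
#'   `a0` and harmonic vectors `a`, `b` (equal length `H >= 1`), so that the
#'   waveform in degrees is
#'   `a0 + sum_h a[h] cos(2 pi h phi) + b[h] sin(2 pi h phi)`.
#' @param cycle_duration Stride time in seconds.
#' @param stance_fraction Fraction of the cycle spent in stance, in (0, 1).
#' @return An object of class `"gait_model"`.
#' @seealso [default_gait_model()], [angle_at_phase()]
#' @export
gait_model <- function(coefficients, cycle_duration, stance_fraction = 0.62) {
  if (!all(c("hip", "knee") %in% names(coefficients))) {
    stop_gv("`coefficients` must have entries 'hip' and 'knee'.",
            class = "gaitverify_domain_error")
  }
  for (j in c("hip", "knee")) {
    cf <- coefficients[[j]]
    if (!all(c("a0", "a", "b") %in% names(cf)) ||
        length(cf$a) != length(cf$b) || length(cf$a) < 1L) {
      stop_gv(sprintf(
        "Coefficients for joint '%s' need a0 and harmonic vectors a, b (H >= 1).",
        j), class = "gaitverify_domain_error")
    }
    check_no_na(c(cf$a0, cf$a, cf$b), sprintf("coefficients$%s", j))
  }
  check_number(cycle_duration, "cycle_duration", lower = 1e-6)
  check_number(stance_fraction, "stance_fraction", lower = 1e-6, upper = 1 - 1e-6)
  structure(list(coefficients = coefficients,
                 cycle_duration = cycle_duration,
                 stance_fraction = stance_fraction),
            class = "gait_model")
}

#' @export
print.gait_model <- function(x, ...) {
  cat("<gait_model>\n")
  cat(sprintf("  cycle duration:  %.3f s\n", x$cycle_duration))
  cat(sprintf("  stance fraction: %.3f\n", x$stance_fraction))
  for (j in names(x$coefficients)) {
    cat(sprintf("  %-4s: H = %d, a0 = %.2f deg\n",
                j, length(x$coefficients[[j]]$a), x$coefficients[[j]]$a0))
  }
  invisible(x)
}

# Raised periodic bump used to sculpt waveform shapes before harmonic
# projection: exp(kappa * (cos(2 pi (phi - center)) - 1)), peak 1 at center.
phase_bump <- function(phi, center, kappa) {
  exp(kappa * (cos(2 * pi * (phi - center)) - 1))
}

# Project a periodic function onto H harmonics by discrete quadrature.
project_harmonics <- function(f, H = 4L, n_grid = 2048L) {
  phi <- (seq_len(n_grid) - 1) / n_grid
  v <- f(phi)
  list(a0 = mean(v),
       a = vapply(seq_len(H), function(h) 2 * mean(v * cos(2 * pi * h * phi)),
                  numeric(1)),
       b = vapply(seq_len(H), function(h) 2 * mean(v * sin(2 * pi * h * phi)),
                  numeric(1)))
}

# Rotate a harmonic set by `shift` in phase: g(phi) = f(phi + shift).
rotate_harmonics <- function(cf, shift) {
  H <- length(cf$a)
  th <- 2 * pi * seq_len(H) * shift
  list(a0 = cf$a0,
       a = cf$a * cos(th) + cf$b * sin(th),
       b = cf$b * cos(th) - cf$a * sin(th))
}

eval_harmonics <- function(cf, phi) {
  out <- rep(cf$a0, length(phi))
  for (h in seq_along(cf$a)) {
    out <- out + cf$a[h] * cos(2 * pi * h * phi) +
      cf$b[h] * sin(2 * pi * h * phi)
  }
  out
}

# Phase of the global minimum of a harmonic set, refined to ~1e-12.
argmin_phase <- function(cf, n_grid = 4096L) {
  phi <- (seq_len(n_grid) - 1) / n_grid
  v <- eval_harmonics(cf, phi)
  i <- which.min(v)
  lo <- phi[i] - 1.5 / n_grid
  hi <- phi[i] + 1.5 / n_grid
  opt <- optimize(function(p) eval_harmonics(cf, p), c(lo, hi),
                  tol = .Machine$double.eps^0.5)
  opt$minimum %% 1
}

#' Default gait model for a given treadmill speed
#'
#' Builds a deterministic hip/knee flexion model with waveform shapes typical
#' of adult treadmill gait: hip flexion roughly -10 to +30 degrees peaking
#' around heel strike, knee flexion with a stance peak (~15-25 degrees) and a
#' swing peak (~50-60 degrees). Shapes are sculpted from smooth periodic
#' bumps, projected onto `H` harmonics, and rotated so the global knee
#' minimum falls exactly at phase 0. Cycle duration decreases and flexion
#' amplitudes increase monotonically with speed.
#'
#' @param speed Treadmill belt speed in m/s (> 0).
#' @param H Number of harmonics retained (default 4).
#' @return A [gait_model()].
#' @export
#' @examples
#' m <- default_gait_model(1.0)
#' angle_at_phase(m, "knee", c(0, 0.25, 0.5, 0.75))
default_gait_model <- function(speed, H = 4L) {
  check_number(speed, "speed", lower = 1e-9)
  check_number(H, "H", lower = 1)

  # stride time shortens and flexion grows modestly with speed
  cycle_duration <- 1.1 * speed^(-0.42)
  stance_fraction <- min(0.72, max(0.55, 0.68 - 0.06 * speed))
  knee_swing_amp <- 52 + 10 * (speed - 1)
  knee_stance_amp <- 16 + 4 * (speed - 1)
  hip_amp <- 20 + 5 * (speed - 1)

  knee_shape <- function(phi) {
    7 + knee_stance_amp * phase_bump(phi, 0.18, 4) +
      knee_swing_amp * phase_bump(phi, 0.72, 5) -
      4 * phase_bump(phi, 0.45, 5) -
      7 * phase_bump(phi, 0.965, 5)
  }
  hip_shape <- function(phi) {
    10 + hip_amp * cos(2 * pi * phi) + 2 * sin(4 * pi * phi)
  }

  knee_cf <- project_harmonics(knee_shape, H = H)
  hip_cf <- project_harmonics(hip_shape, H = H)

  # anchor the cycle start at the knee-flexion global minimum
  shift <- argmin_phase(knee_cf)
  knee_cf <- rotate_harmonics(knee_cf, shift)
  hip_cf <- rotate_harmonics(hip_cf, shift)

  gait_model(list(hip = hip_cf, knee = knee_cf),
             cycle_duration = cycle_duration,
             stance_fraction = stance_fraction)
}

#' Evaluate a gait model at given phases
#'
#' @param model A [gait_model()].
#' @param joint `"hip"` or `"knee"`.
#' @param phase Numeric vector of gait phases; any real value (wrapped mod 1).
#' @return Joint flexion angle(s) in degrees, flexion positive.
#' @export
angle_at_phase <- function(model, joint, phase) {
  stopifnot(inherits(model, "gait_model"))
  if (!joint %in% names(model$coefficients)) {
    stop_gv(sprintf("Unknown joint '%s'; model has: %s.", joint,
                    paste(names(model$coefficients), collapse = ", ")),
            class = "gaitverify_domain_error")
  }
  check_no_na(phase, "phase")
  eval_harmonics(model$coefficients[[joint]], phase %% 1)
}

#' Perturb a gait model by amplitude scale and offset
#'
#' Scales all harmonics of each joint by a common positive factor, shifts the
#' constant term, and rescales the cycle duration. Because the waveform
#' transform is monotone, extremum phases -- in particular the knee-minimum
#' anchor at phase 0 -- are preserved exactly. This is the transform used to
#' create between-participant and between-session variation.
#'
#' @param model A [gait_model()].
#' @param scale Named positive amplitude factors (per joint).
#' @param offset Named additive offsets in degrees (per joint).
#' @param cycle_scale Multiplier on the cycle duration.
#' @return A perturbed [gait_model()].
#' @export
perturb_gait_model <- function(model, scale = c(hip = 1, knee = 1),
                               offset = c(hip = 0, knee = 0),
                               cycle_scale = 1) {
  cfs <- model$coefficients
  for (j in names(cfs)) {
    s <- if (j %in% names(scale)) scale[[j]] else 1
    o <- if (j %in% names(offset)) offset[[j]] else 0
    if (s <= 0) {
      stop_gv("Amplitude scale must be positive to preserve waveform shape.",
              class = "gaitverify_domain_error")
    }
    cfs[[j]]$a <- cfs[[j]]$a * s
    cfs[[j]]$b <- cfs[[j]]$b * s
    cfs[[j]]$a0 <- cfs[[j]]$a0 + o
  }
  gait_model(cfs, cycle_duration = model$cycle_duration * cycle_scale,
             stance_fraction = model$stance_fraction)
}

#' Ground-truth discrete parameters of a gait model
#'
#' Maximum, minimum and range of motion in degrees per joint, from a dense
#' phase grid. Every synthetic cycle of the model shares these values.
#'
#' @param model A [gait_model()].
#' @param n_grid Phase-grid resolution.
#' @return A tibble `joint, max_deg, min_deg, rom_deg`.
#' @export
true_discrete_params <- function(model, n_grid = 4096L) {
  phi <- (seq_len(n_grid) - 1) / n_grid
  purrr::map_dfr(names(model$coefficients), function(j) {
    v <- angle_at_phase(model, j, phi)
    tibble(joint = j, max_deg = max(v), min_deg = min(v),
           rom_deg = max(v) - min(v))
  })
}
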