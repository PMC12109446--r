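#' Describe one synthetic walking trial
#'
#' A gait profile holds the generative parameters for one simulated
#' thigh-mounted smartphone recording: how fast the subject walks, what share
#' of each stride is spent in ground contact, how long the trial is, and how
#' noisy the sensors are. Profiles are consumed by [simulate_recording()].
#'
#' The implied stride time is `120 / cadence_spm` seconds (two steps per
#' stride). When `stride_length_m` is `NULL` it is derived from the stride
#' frequency `f = cadence_spm / 120` via the package's default calibration
#' `0.5 + 0.85 * f` metres, which places a 100 steps/min walker at about
#' 1.21 m per stride — typical for healthy adults.
#'
#' @param cadence_spm Walking cadence in steps per minute. Must be positive.
#' @param stance_fraction Fraction of the stride spent in stance, strictly
#'   between 0 and 1. Healthy level walking sits near 0.6.
#' @param speed_condition One of `"normal"`, `"low"`, `"high"`; self-selected
#'   speed category. Low/high scale cadence and stride length by 0.8 / 1.25
#'   and inflate sensor noise by 1.5, reflecting that off-normal speeds are
#'   harder for event detection.
#' @param stride_length_m True stride length in metres, or `NULL` to derive
#'   it from cadence (see Details).
#' @param n_cycles Number of gait cycles to simulate (the study protocol used
#'   six cycles per trial).
#' @param asymmetry Cycle-to-cycle variability scale (>= 0): the SD of the
#'   multiplicative jitter applied to each stride duration. Dual-task and
#'   pathological gait are emulated by raising it.
#' @param noise_sd Additive white measurement noise SD, in channel units.
#' @param drift_sd Per-sample SD of the random-walk sensor drift.
#' @param seed Integer seed making the trial reproducible, or `NULL`.
#' @param amp_scale Optional named numeric vector of per-channel amplitude
#'   multipliers (subject-to-subject morphology variation).
#'
#' @return An object of class `gait_profile` (a validated list).
#' @examples
#' gait_profile(cadence_spm = 100, stance_fraction = 0.6, seed = 1)
#' @export
gait_profile <- function(cadence_spm = 100,
                         stance_fraction = 0.60,
                         speed_condition = c("normal", "low", "high"),
                         stride_length_m = NULL,
                         n_cycles = 6,
                         asymmetry = 0.02,
                         noise_sd = 0.05,
                         drift_sd = 0.002,
                         seed = NULL,
                         amp_scale = NULL) {
  speed_condition <- match.arg(speed_condition)
  stop_if_not_scalar_number(cadence_spm, "cadence_spm", positive = TRUE)
  check_fraction(stance_fraction, "stance_fraction")
  stop_if_not_scalar_number(n_cycles, "n_cycles")
  if (n_cycles < 1 || n_cycles != round(n_cycles)) {
    abort("`n_cycles` must be a whole number >= 1.")
  }
  stop_if_not_scalar_number(asymmetry, "asymmetry")
  if (asymmetry < 0) abort("`asymmetry` must be >= 0.")
  stop_if_not_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  stop_if_not_scalar_number(drift_sd, "drift_sd")
  if (drift_sd < 0) abort("`drift_sd` must be >= 0.")
  if (!is.null(stride_length_m)) {
    stop_if_not_scalar_number(stride_length_m, "stride_length_m", positive = TRUE)
  }
  if (!is.null(amp_scale)) {
    if (is.null(names(amp_scale)) || !all(names(amp_scale) %in% GAIT_CHANNELS)) {
      abort("`amp_scale` must be a named vector over the nine channel names.")
    }
  }

  structure(
    list(
      cadence_spm = cadence_spm,
      stance_fraction = stance_fraction,
      speed_condition = speed_condition,
      stride_length_m = stride_length_m,
      n_cycles = as.integer(n_cycles),
      asymmetry = asymmetry,
      noise_sd = noise_sd,
      drift_sd = drift_sd,
      seed = if (is.null(seed)) NULL else as.integer(seed),
      amp_scale = amp_scale
    ),
    class = "gait_profile"
  )
}

#' @export
print.gait_profile <- function(x, ...) {
  cat("<gait_profile>\n")
  cat(sprintf(
    "  cadence %.2f steps/min (stride %.3f s), stance fraction %.3f\n",
    x$cadence_spm, 120 / x$cadence_spm, x$stance_fraction
  ))
  cat(sprintf(
    "  speed %s, %d cycles, asymmetry %.3f, noise sd %.3f, drift sd %.4f\n",
    x$speed_condition, x$n_cycles, x$asymmetry, x$noise_sd, x$drift_sd
  ))
  invisible(x)
}

# Multipliers attached to the self-selected speed categories. Low and high
# speeds perturb both the gait geometry and the sensor noise level.
speed_multipliers <- function(speed_condition) {
  switch(speed_condition,
    low = list(cadence = 0.8, stride_length = 0.8, noise = 1.5),
    normal = list(cadence = 1.0, stride_length = 1.0, noise = 1.0),
    high = list(cadence = 1.25, stride_length = 1.25, noise = 1.5),
    abort("Unknown speed condition.")
  )
}

#' Default dual-task perturbations
#'
#' Effect magnitudes applied to a profile when simulating cognitive (VFT) or
#' physical (PTW) dual-task walking, relative to single-task walking (STW).
#' Directions follow the consistent clinical picture: dual tasks slow cadence,
#' prolong stance, shorten strides and increase cycle-to-cycle variability.
#'
#' @return A named list with one entry per task; each entry holds
#'   `cadence_mult`, `stance_shift`, `stride_length_mult` and `asymmetry_mult`.
#' @export
dual_task_effects <- function() {
  list(
    STW = list(cadence_mult = 1.00, stance_shift = 0.000,
               stride_length_mult = 1.00, asymmetry_mult = 1.0),
    VFT = list(cadence_mult = 0.85, stance_shift = 0.042,
               stride_length_mult = 0.95, asymmetry_mult = 2.0),
    PTW = list(cadence_mult = 0.91, stance_shift = 0.027,
               stride_length_mult = 0.95, asymmetry_mult = 1.5)
  )
}

# Resolve the effective generative parameters of a profile once speed and
# task modifiers are applied. Stride length defaults to the package's
# frequency calibration when unset.
resolve_profile <- function(profile, task = "STW", effects = dual_task_effects()) {
  if (!task %in% names(effects)) {
    abort(sprintf("Unknown task `%s`; expected one of %s.",
                  task, paste(names(effects), collapse = ", ")))
  }
  sp <- speed_multipliers(profile$speed_condition)
  ef <- effects[[task]]

  cadence <- profile$cadence_spm * sp$cadence * ef$cadence_mult
  stance <- min(profile$stance_fraction + ef$stance_shift, 0.95)
  stride_time <- 120 / cadence
  freq <- 1 / stride_time
  stride_len <- profile$stride_length_m
  if (is.null(stride_len)) {
    # Derived lengths follow the calibration at the *effective* stride
    # frequency, so speed categories move stride length automatically and
    # the whole cohort obeys one linear length-frequency law.
    stride_len <- 0.5 + 0.85 * freq
  } else {
    stride_len <- stride_len * sp$stride_length
  }
  stride_len <- stride_len * ef$stride_length_mult

  list(
    cadence_spm = cadence,
    stance_fraction = stance,
    stride_time_s = stride_time,
    stride_length_m = stride_len,
    n_cycles = profile$n_cycles,
    asymmetry = profile$asymmetry * ef$asymmetry_mult,
    noise_sd = profile$noise_sd * sp$noise,
    drift_sd = profile$drift_sd,
    amp_scale = profile$amp_scale
  )
}
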