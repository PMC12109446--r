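#' Simulate a thigh-mounted smartphone walking recording
#'
#' Generates one synthetic walking trial with the statistical structure of a
#' 50 Hz thigh-mounted smartphone recording: nine sensor channels
#' (`Ax, Ay, Az, Gx, Gy, Gz, Yaw, Pitch, Roll`), a binary stance reference
#' trace (1 = stance, 0 = swing) as an insole pressure sensor would provide,
#' and the exact, real-valued ground-truth heel-strike / toe-off times.
#'
#' Six channels (`Ax, Ay, Gy, Gz, Yaw, Roll`) carry gait-locked periodic
#' structure: a three-harmonic Fourier series of the stride frequency, phase
#' locked to heel strike, plus a heel-strike impact transient on `Ay`. The
#' remaining three (`Az, Gx, Pitch`) vary little during level walking and
#' carry only a constant offset plus low-amplitude noise, which is what makes
#' the preprocessing stage's channel-exclusion rule reproducible on synthetic
#' data. White noise and random-walk drift are added to every channel.
#'
#' The recording spans `n_cycles` strides and starts half a swing before the
#' first heel strike, so every true event — including the first heel strike —
#' is recoverable from the binary stance trace. Event times are real-valued;
#' the stance trace assigns sample `i` (at time `t_i = (i-1)/fs`) to stance
#' when `t_i` falls in a stance interval, i.e. the label grid is quantized to
#' the 50 Hz insole clock while ground truth stays sub-sample exact.
#'
#' @param profile A [gait_profile()].
#' @param task Walking task: `"STW"` (single task), `"VFT"` (cognitive dual
#'   task) or `"PTW"` (physical dual task). Dual tasks perturb the profile
#'   via [dual_task_effects()].
#' @param subject_id,age_group Metadata labels carried through the pipeline.
#' @param fs_hz Sampling rate in Hz (the smartphone platform caps it at 50).
#' @param effects Dual-task effect magnitudes, see [dual_task_effects()].
#'
#' @return A `gait_recording`: list with `signals` (tibble: `time`, nine
#'   channels, `stance`), `events` (tibble: `event` in `{"HS","TO"}`,
#'   `time_s`), `fs_hz`, and `meta`.
#' @examples
#' rec <- simulate_recording(gait_profile(seed = 1))
#' rec
#' @export
simulate_recording <- function(profile,
                               task = "STW",
                               subject_id = "S01",
                               age_group = NA_character_,
                               fs_hz = 50,
                               effects = dual_task_effects()) {
  if (!inherits(profile, "gait_profile")) {
    abort("`profile` must be a `gait_profile` object.")
  }
  stop_if_not_scalar_number(fs_hz, "fs_hz", positive = TRUE)
  p <- resolve_profile(profile, task = task, effects = effects)

  with_local_seed(profile$seed, {
    # Per-cycle stride durations and stance fractions with multiplicative
    # jitter; clamped away from degenerate values.
    jit_t <- 1 + p$asymmetry * rnorm(p$n_cycles)
    jit_s <- 1 + 0.5 * p$asymmetry * rnorm(p$n_cycles)
    stride_i <- pmax(p$stride_time_s * jit_t, 0.3 * p$stride_time_s)
    stance_i <- pmin(pmax(p$stance_fraction * jit_s, 0.05), 0.95)

    # Event geometry: heel strikes delimit cycles; recording leads in by
    # half of the first swing so the first heel strike is an observable
    # swing-to-stance transition.
    lead <- 0.5 * (1 - stance_i[1]) * stride_i[1]
    hs <- lead + c(0, cumsum(stride_i))[seq_len(p$n_cycles)]
    to <- hs + stance_i * stride_i
    duration <- sum(stride_i)
    n <- ceiling(duration * fs_hz)
    t <- (seq_len(n) - 1) / fs_hz

    # Stride phase in [0, 2*pi) locked to heel strikes; samples before the
    # first heel strike extend the first cycle's phase backwards.
    cyc <- findInterval(t, hs)
    cyc0 <- pmax(cyc, 1L)
    theta <- 2 * pi * (t - hs[cyc0]) / stride_i[cyc0]

    amp_of <- function(ch) {
      s <- p$amp_scale
      if (!is.null(s) && ch %in% names(s)) s[[ch]] else 1
    }

    harmonics <- function(amp, phase, scale) {
      scale * (amp[1] * sin(theta + phase[1]) +
                 amp[2] * sin(2 * theta + phase[2]) +
                 amp[3] * sin(3 * theta + phase[3]))
    }
    # Wrapped phase distance to heel strike, for the Ay impact transient.
    wrap <- ((theta + pi) %% (2 * pi)) - pi
    bump <- exp(-0.5 * (wrap / 0.3)^2)

    noise <- function(sd_w) {
      rnorm(n, 0, sd_w) + cumsum(rnorm(n, 0, p$drift_sd))
    }

    sig <- tibble::tibble(
      time = t,
      Ax = harmonics(c(1.0, 0.5, 0.20), c(0.0, 0.7, 1.9), amp_of("Ax")) +
        noise(p$noise_sd),
      Ay = harmonics(c(1.2, 0.6, 0.30), c(1.1, 2.0, 0.4), amp_of("Ay")) +
        1.5 * amp_of("Ay") * bump + noise(p$noise_sd),
      Az = 9.81 + noise(0.4 * p$noise_sd),
      Gx = 0.15 + noise(0.4 * p$noise_sd),
      Gy = harmonics(c(0.9, 0.7, 0.25), c(2.3, 0.9, 2.8), amp_of("Gy")) +
        noise(p$noise_sd),
      Gz = harmonics(c(0.8, 0.4, 0.30), c(4.0, 1.5, 0.2), amp_of("Gz")) +
        noise(p$noise_sd),
      Yaw = harmonics(c(1.1, 0.3, 0.15), c(5.1, 3.3, 1.0), amp_of("Yaw")) +
        noise(p$noise_sd),
      Pitch = -0.35 + noise(0.4 * p$noise_sd),
      Roll = harmonics(c(1.0, 0.45, 0.20), c(2.9, 4.4, 5.6), amp_of("Roll")) +
        noise(p$noise_sd),
      stance = {
        idx <- findInterval(t, hs)
        as.integer(idx >= 1 & t < to[pmax(idx, 1L)])
      }
    )

    events <- tibble::tibble(
      event = rep(c("HS", "TO"), p$n_cycles),
      time_s = as.vector(rbind(hs, to))
    )

    structure(
      list(
        signals = sig,
        events = events,
        fs_hz = fs_hz,
        meta = list(
          subject_id = subject_id,
          age_group = age_group,
          speed_condition = profile$speed_condition,
          task = task
        ),
        profile = profile
      ),
      class = "gait_recording"
    )
  })
}

#' @export
print.gait_recording <- function(x, ...) {
  n <- nrow(x$signals)
  cat("<gait_recording>\n")
  cat(sprintf(
    "  subject %s | %s | %s speed | %d samples @ %g Hz (%.2f s)\n",
    x$meta$subject_id, x$meta$task, x$meta$speed_condition,
    n, x$fs_hz, n / x$fs_hz
  ))
  cat(sprintf(
    "  channels: %s%s\n",
    paste(recording_channels(x), collapse = ", "),
    if ("stance" %in% names(x$signals)) " (+ stance reference)" else ""
  ))
  if (!is.null(x$events) && nrow(x$events) > 0) {
    cat(sprintf(
      "  true events: %d HS, %d TO\n",
      sum(x$events$event == "HS"), sum(x$events$event == "TO")
    ))
  }
  invisible(x)
}

#' Simulate a cohort of walking recordings
#'
#' Draws per-subject gait profiles from uniform parameter ranges and
#' generates one recording per subject x speed condition x task. Subjects
#' are tagged with an age-group label from six decade bands, either cycling
#' through the bands or following an explicit per-band allocation — the
#' stratification the dataset splitter later respects.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param speeds Character vector of speed conditions to record per subject.
#' @param tasks Character vector of walking tasks per subject.
#' @param cadence_range,stance_fraction_range Length-2 numeric ranges
#'   (`c(lo, hi)`, `lo <= hi`) that subject-level cadence (steps/min) and
#'   stance fraction are drawn from.
#' @param n_cycles,asymmetry,noise_sd,drift_sd Passed to every profile.
#' @param age_groups Labels of the six age bands.
#' @param age_allocation Optional integer vector, one count per age band,
#'   summing to `n_subjects`; `NULL` cycles subjects through the bands.
#' @param seed Root seed; the whole cohort is reproducible from it.
#'
#' @return A `gait_cohort`: list of `gait_recording`s with a `manifest`
#'   attribute; see [cohort_manifest()].
#' @examples
#' coh <- simulate_cohort(6, seed = 1)
#' cohort_manifest(coh)
#' @export
simulate_cohort <- function(n_subjects,
                            speeds = "normal",
                            tasks = "STW",
                            cadence_range = c(90, 110),
                            stance_fraction_range = c(0.58, 0.66),
                            n_cycles = 6,
                            asymmetry = 0.02,
                            noise_sd = 0.05,
                            drift_sd = 0.002,
                            age_groups = c("20-29", "30-39", "40-49",
                                           "50-59", "60-69", "70-79"),
                            age_allocation = NULL,
                            seed = 1) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    abort("`n_subjects` must be >= 1.")
  }
  n_subjects <- as.integer(n_subjects)
  check_range <- function(r, name) {
    if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]) {
      abort(sprintf("`%s` must be a finite numeric range c(lo, hi) with lo <= hi.", name))
    }
  }
  check_range(cadence_range, "cadence_range")
  check_range(stance_fraction_range, "stance_fraction_range")

  if (is.null(age_allocation)) {
    tags <- age_groups[((seq_len(n_subjects) - 1L) %% length(age_groups)) + 1L]
  } else {
    if (length(age_allocation) != length(age_groups) ||
        sum(age_allocation) != n_subjects) {
      abort("`age_allocation` must give one count per age band and sum to `n_subjects`.")
    }
    tags <- rep(age_groups, times = age_allocation)
  }

  recs <- with_local_seed(seed, {
    cadence <- runif(n_subjects, cadence_range[1], cadence_range[2])
    stancef <- runif(n_subjects, stance_fraction_range[1], stance_fraction_range[2])
    amp <- replicate(n_subjects,
                     setNames(runif(9, 0.8, 1.2), GAIT_CHANNELS),
                     simplify = FALSE)
    sub_seed <- sample.int(.Machine$integer.max - 1L,
                           n_subjects * length(speeds) * length(tasks))
    out <- vector("list", n_subjects * length(speeds) * length(tasks))
    k <- 0L
    for (i in seq_len(n_subjects)) {
      sid <- sprintf("S%03d", i)
      for (task in tasks) {
        for (sp in speeds) {
          k <- k + 1L
          prof <- gait_profile(
            cadence_spm = cadence[i],
            stance_fraction = stancef[i],
            speed_condition = sp,
            n_cycles = n_cycles,
            asymmetry = asymmetry,
            noise_sd = noise_sd,
            drift_sd = drift_sd,
            seed = sub_seed[k],
            amp_scale = amp[[i]]
          )
          out[[k]] <- simulate_recording(
            prof, task = task, subject_id = sid, age_group = tags[i]
          )
        }
      }
    }
    out
  })

  structure(recs, class = "gait_cohort")
}

#' Summarize a cohort as a tibble
#'
#' @param cohort A `gait_cohort` from [simulate_cohort()].
#' @return One row per recording: subject, age group, speed, task, duration,
#'   sample and event counts.
#' @export
cohort_manifest <- function(cohort) {
  purrr::map_dfr(cohort, function(r) {
    tibble::tibble(
      subject_id = r$meta$subject_id,
      age_group = r$meta$age_group,
      speed_condition = r$meta$speed_condition,
      task = r$meta$task,
      n_samples = nrow(r$signals),
      duration_s = nrow(r$signals) / r$fs_hz,
      n_events = if (is.null(r$events)) 0L else nrow(r$events)
    )
  })
}

#' @export
print.gait_cohort <- function(x, ...) {
  m <- cohort_manifest(x)
  cat(sprintf(
    "<gait_cohort> %d recordings, %d subjects, tasks: %s, speeds: %s\n",
    nrow(m), dplyr::n_distinct(m$subject_id),
    paste(unique(m$task), collapse = "/"),
    paste(unique(m$speed_condition), collapse = "/")
  ))
  invisible(x)
}
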