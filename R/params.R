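#' Segment an event sequence into gait cycles
#'
#' A gait cycle runs from one heel strike to the next heel strike of the
#' same (instrumented) leg, with exactly one toe-off strictly in between.
#' Stretches violating that pattern — a missing toe-off between two heel
#' strikes, doubled events — are skipped and counted rather than guessed at.
#'
#' @param events Event tibble (`event` in `{"HS","TO"}`, `time_s`),
#'   time-sorted.
#' @return A tibble with columns `hs_start`, `to`, `hs_end` (seconds), one
#'   row per complete cycle, with attribute `n_skipped` counting the
#'   malformed heel-strike intervals. Fewer than two heel strikes yield zero
#'   rows.
#' @examples
#' ev <- tibble::tibble(event = c("HS", "TO", "HS"), time_s = c(0, 0.76, 1.18))
#' segment_cycles(ev)
#' @export
segment_cycles <- function(events) {
  if (!all(c("event", "time_s") %in% names(events))) {
    abort("`events` must have columns `event` and `time_s`.")
  }
  events <- dplyr::arrange(events, .data$time_s)
  hs <- events$time_s[events$event == "HS"]
  to <- events$time_s[events$event == "TO"]
  out <- list()
  skipped <- 0L
  if (length(hs) >= 2) {
    for (i in seq_len(length(hs) - 1L)) {
      mid <- to[to > hs[i] & to < hs[i + 1L]]
      if (length(mid) == 1L) {
        out[[length(out) + 1L]] <- tibble::tibble(
          hs_start = hs[i], to = mid, hs_end = hs[i + 1L]
        )
      } else {
        skipped <- skipped + 1L
      }
    }
  }
  res <- if (length(out) == 0) {
    tibble::tibble(hs_start = double(), to = double(), hs_end = double())
  } else {
    dplyr::bind_rows(out)
  }
  attr(res, "n_skipped") <- skipped
  res
}

#' Speed-adaptive stride-length model
#'
#' A linear map from stride frequency (Hz, i.e. `1 / stride_time`) to stride
#' length (m). Stride frequency — rather than walking speed — is the
#' regressor, which breaks the circularity that walking speed is itself
#' computed as stride length over stride time. Predictions are clipped to
#' the physiological range \[0.2, 2.5\] m.
#'
#' `default_stride_model()` ships the package's calibration
#' `length = 0.5 + 0.85 * f`, obtained from the synthetic cohort's ground
#' truth; [fit_stride_length_model()] re-calibrates it from data.
#'
#' @param intercept_m Intercept in metres.
#' @param slope_m_per_hz Slope in metres per Hz of stride frequency.
#' @return A `stride_length_model`.
#' @export
stride_length_model <- function(intercept_m, slope_m_per_hz) {
  stop_if_not_scalar_number(intercept_m, "intercept_m")
  stop_if_not_scalar_number(slope_m_per_hz, "slope_m_per_hz")
  structure(
    list(intercept_m = intercept_m, slope_m_per_hz = slope_m_per_hz,
         fit = NULL),
    class = "stride_length_model"
  )
}

#' @rdname stride_length_model
#' @export
default_stride_model <- function() stride_length_model(0.5, 0.85)

#' @export
print.stride_length_model <- function(x, ...) {
  cat(sprintf(
    "<stride_length_model> length = %.4f + %.4f * stride_frequency [m]%s\n",
    x$intercept_m, x$slope_m_per_hz,
    if (is.null(x$fit)) " (fixed calibration)" else " (fitted)"
  ))
  invisible(x)
}

#' @export
predict.stride_length_model <- function(object, stride_frequency_hz, ...) {
  pmin(pmax(object$intercept_m + object$slope_m_per_hz * stride_frequency_hz,
            0.2), 2.5)
}

#' Calibrate the stride-length model by ordinary least squares
#'
#' Regresses known stride lengths on stride frequency across trials.
#'
#' @param trials A data frame with columns `stride_frequency_hz` and
#'   `stride_length_m` (one row per trial or cycle).
#' @return A fitted `stride_length_model`; `tidy()` and `glance()` expose
#'   the underlying [lm()] fit.
#' @examples
#' d <- tibble::tibble(stride_frequency_hz = c(0.7, 0.8, 0.9),
#'                     stride_length_m = 0.5 + 0.6 * c(0.7, 0.8, 0.9))
#' fit_stride_length_model(d)
#' @export
fit_stride_length_model <- function(trials) {
  if (!all(c("stride_frequency_hz", "stride_length_m") %in% names(trials))) {
    abort("`trials` needs columns `stride_frequency_hz` and `stride_length_m`.")
  }
  if (nrow(trials) < 2 || dplyr::n_distinct(trials$stride_frequency_hz) < 2) {
    abort("Need at least two distinct stride frequencies to fit the model.")
  }
  fit <- lm(stride_length_m ~ stride_frequency_hz, data = trials)
  out <- stride_length_model(unname(coef(fit)[1]), unname(coef(fit)[2]))
  out$fit <- fit
  out
}

#' @export
tidy.stride_length_model <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(
      term = c("(Intercept)", "stride_frequency_hz"),
      estimate = c(x$intercept_m, x$slope_m_per_hz)
    ))
  }
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @export
glance.stride_length_model <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(r.squared = NA_real_, sigma = NA_real_,
                          nobs = NA_integer_))
  }
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    nobs = length(s$residuals)
  )
}

#' Compute spatiotemporal gait parameters from cycles
#'
#' Per cycle: stride time is heel-strike to heel-strike; stance time is heel
#' strike to toe-off; swing time the remainder; stance/swing phase their
#' percentages of the stride (summing to 100 exactly); cadence is
#' `120 / stride_time` (two steps per stride); stride length comes from the
#' stride-length model evaluated at the cycle's stride frequency; and
#' walking speed is stride length over stride time. The trial value of each
#' parameter is the unweighted mean over complete cycles.
#'
#' @param cycles A cycle tibble from [segment_cycles()].
#' @param stride_model A `stride_length_model`.
#' @param per_cycle If `TRUE`, return one row per cycle instead of the
#'   trial means.
#' @return A tibble with columns `cadence_spm`, `stride_time_s`,
#'   `stance_phase_pct`, `swing_phase_pct`, `stance_time_s`, `swing_time_s`,
#'   `stride_length_m`, `walking_speed_mps` (plus `n_cycles` on the
#'   trial-mean row).
#' @examples
#' cyc <- tibble::tibble(hs_start = 0, to = 0.76, hs_end = 1.18)
#' compute_parameters(cyc)
#' @export
compute_parameters <- function(cycles, stride_model = default_stride_model(),
                               per_cycle = FALSE) {
  if (nrow(cycles) < 1) abort("Need at least one complete gait cycle.")
  if (any(cycles$hs_end <= cycles$hs_start) ||
      any(cycles$to <= cycles$hs_start) || any(cycles$hs_end <= cycles$to)) {
    abort("Each cycle must satisfy hs_start < to < hs_end.")
  }
  pc <- dplyr::mutate(
    cycles,
    stride_time_s = .data$hs_end - .data$hs_start,
    stance_time_s = .data$to - .data$hs_start,
    swing_time_s = .data$hs_end - .data$to,
    stance_phase_pct = 100 * .data$stance_time_s / .data$stride_time_s,
    swing_phase_pct = 100 - .data$stance_phase_pct,
    cadence_spm = 120 / .data$stride_time_s,
    stride_length_m = predict(stride_model, 1 / .data$stride_time_s),
    walking_speed_mps = .data$stride_length_m / .data$stride_time_s
  )
  cols <- c("cadence_spm", "stride_time_s", "stance_phase_pct",
            "swing_phase_pct", "stance_time_s", "swing_time_s",
            "stride_length_m", "walking_speed_mps")
  if (per_cycle) {
    return(pc[, c("hs_start", "to", "hs_end", cols)])
  }
  out <- dplyr::summarise(pc, dplyr::across(dplyr::all_of(cols), mean))
  out$n_cycles <- nrow(pc)
  out
}

#' Gait parameters straight from a recording
#'
#' Composes event detection (or the recording's reference events),
#' [segment_cycles()] and [compute_parameters()], and prefixes the result
#' with the recording's metadata — the row format the dual-task comparison
#' expects.
#'
#' @param rec A `gait_recording`.
#' @param events Optional event tibble; defaults to the recording's stored
#'   true events.
#' @param stride_model A `stride_length_model`.
#' @return A one-row tibble: `subject_id`, `age_group`, `speed_condition`,
#'   `task`, then the eight gait parameters and `n_cycles`.
#' @export
recording_parameters <- function(rec, events = NULL,
                                 stride_model = default_stride_model()) {
  assert_recording(rec)
  events <- events %||% rec$events
  if (is.null(events)) abort("No events available for this recording.")
  cycles <- segment_cycles(events)
  if (nrow(cycles) == 0) abort("No complete gait cycles in the event sequence.")
  dplyr::bind_cols(
    tibble::tibble(
      subject_id = rec$meta$subject_id %||% NA_character_,
      age_group = rec$meta$age_group %||% NA_character_,
      speed_condition = rec$meta$speed_condition %||% NA_character_,
      task = rec$meta$task %||% NA_character_
    ),
    compute_parameters(cycles, stride_model = stride_model)
  )
}
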