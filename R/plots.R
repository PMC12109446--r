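# ggplot2 display methods for the package's result types.

#' @export
autoplot.gait_recording <- function(object, channels = NULL, ...) {
  chans <- channels %||% recording_channels(object)
  long <- tidyr::pivot_longer(
    object$signals[, c("time", chans)],
    cols = dplyr::all_of(chans),
    names_to = "channel", values_to = "value"
  )
  long$channel <- factor(long$channel, levels = GAIT_CHANNELS)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value))
  if ("stance" %in% names(object$signals)) {
    st <- extract_events(object$signals$stance, fs_hz = object$fs_hz,
                         t0 = object$signals$time[1])
    hs <- st$time_s[st$event == "HS"]
    p <- p + ggplot2::geom_vline(xintercept = hs, linetype = "dotted",
                                 colour = "grey50")
  }
  p +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL,
                  title = sprintf("%s | %s | %s speed",
                                  object$meta$subject_id, object$meta$task,
                                  object$meta$speed_condition))
}

#' Plot a stance-probability trace against the reference label
#'
#' The model's continuous output in \[0, 1\] overlaid on the binary stance
#' reference — the standard visual check that predicted phase transitions
#' line up with the insole label.
#'
#' @param trace A trace tibble from [predict_trace()].
#' @param rec The matching `gait_recording` (for the stance reference);
#'   optional.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, rec = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time,
                                           y = .data$stance_prob))
  if (!is.null(rec) && "stance" %in% names(rec$signals)) {
    ref <- rec$signals[rec$signals$time >= min(trace$time), ]
    p <- p + ggplot2::geom_step(
      data = ref, ggplot2::aes(x = .data$time, y = .data$stance),
      colour = "grey60"
    )
  }
  p +
    ggplot2::geom_line(colour = "#2166AC") +
    ggplot2::labs(x = "time [s]", y = "stance probability")
}

#' @export
autoplot.gait_model <- function(object, ...) {
  h <- tidy(object)
  if (nrow(h) == 0) abort("Model has no training history to plot.")
  long <- tidyr::pivot_longer(h, cols = c("train_loss", "val_loss"),
                              names_to = "set", values_to = "mae")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$mae,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "MAE", colour = NULL,
                  title = object$cfg$architecture)
}

#' @export
autoplot.bland_altman <- function(object, ...) {
  d <- attr(object, "data")
  pooled <- object[object$group == "(pooled)", ]
  if (nrow(pooled) == 0) pooled <- object[1, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean, y = .data$diff,
                                  colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = pooled$bias, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_hline(yintercept = c(pooled$loa_lower, pooled$loa_upper),
                        linetype = "dashed", colour = "#B2182B") +
    ggplot2::labs(x = "mean of pair", y = "difference (detected - reference)",
                  colour = NULL)
}

#' @export
autoplot.gait_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$speed_condition, y = .data$mae_ms,
                               fill = .data$event)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "speed condition", y = "event timing MAE [ms]",
                  fill = NULL)
}
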