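#' Threshold and debounce a stance-probability trace
#'
#' Converts a continuous stance-probability trace into a clean binary
#' stance/swing signal: values are thresholded at `threshold` (0.5 by
#' default — the natural decision point when the model was trained against
#' 0/1 labels), then runs of constant value shorter than `min_phase_ms` are
#' merged into their neighbours by flipping the short run, processing
#' leftmost-first. The default 100 ms floor rules out physiologically
#' impossible stance or swing phases.
#'
#' @param trace Numeric vector with values in `[0, 1]` (a `stance_prob`
#'   column from [predict_trace()] works directly).
#' @param threshold Stance decision threshold.
#' @param min_phase_ms Minimum credible phase duration in milliseconds.
#' @param fs_hz Sampling rate of the trace.
#' @return An integer 0/1 vector of the same length.
#' @examples
#' binarize_trace(c(0.1, 0.9, 0.1), fs_hz = 50) # 20 ms spike removed
#' @export
binarize_trace <- function(trace, threshold = 0.5, min_phase_ms = 100,
                           fs_hz = 50) {
  if (is.data.frame(trace)) trace <- trace$stance_prob
  if (any(!is.finite(trace)) || any(trace < 0) || any(trace > 1)) {
    abort("`trace` values must be finite and within [0, 1].")
  }
  check_fraction(threshold, "threshold")
  b <- as.integer(trace >= threshold)
  min_len <- max(1L, round(min_phase_ms / 1000 * fs_hz))
  if (min_len <= 1L || length(b) == 0) return(b)
  repeat {
    r <- rle(b)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < min_len)
    if (length(short) == 0) break
    i <- short[1]
    start <- if (i == 1L) 1L else sum(r$lengths[1:(i - 1L)]) + 1L
    end <- start + r$lengths[i] - 1L
    b[start:end] <- 1L - r$values[i]
  }
  b
}

#' Extract gait events from a binary stance signal
#'
#' A heel strike is a 0-to-1 (swing-to-stance) transition and a toe-off a
#' 1-to-0 transition; each event is timestamped at the first sample of the
#' new phase (matching the first-contact semantics of an insole pressure
#' sensor), i.e. sample `k` maps to time `t0 + (k - 1) / fs_hz`.
#'
#' @param binary Integer/numeric vector of 0s and 1s.
#' @param fs_hz Sampling rate.
#' @param t0 Time of the first sample, in seconds.
#' @return A tibble with columns `event` (`"HS"` or `"TO"`) and `time_s`,
#'   sorted by time; zero rows for a constant signal.
#' @examples
#' extract_events(c(0, 0, 1, 1, 1, 0, 0), fs_hz = 50)
#' @export
extract_events <- function(binary, fs_hz = 50, t0 = 0) {
  if (!all(binary %in% c(0, 1))) abort("`binary` must contain only 0 and 1.")
  if (length(binary) < 2) {
    return(tibble::tibble(event = character(), time_s = double()))
  }
  d <- diff(binary)
  hs <- which(d == 1) + 1L
  to <- which(d == -1) + 1L
  out <- tibble::tibble(
    event = c(rep("HS", length(hs)), rep("TO", length(to))),
    time_s = t0 + (c(hs, to) - 1) / fs_hz
  )
  dplyr::arrange(out, .data$time_s)
}

#' Match predicted events to reference events and score timing error
#'
#' Greedy nearest-neighbour matching per event kind: candidate pairs within
#' `max_gap_ms` are accepted in order of increasing absolute time
#' difference, each event used at most once, and kinds are never
#' cross-matched. The per-kind mean absolute error (MAE) in milliseconds is
#' computed over the matched pairs; unmatched reference events and spurious
#' predictions are counted but never pollute the MAE. The default 250 ms
#' gap is about half a swing phase and prevents pairing across gait cycles.
#'
#' @param reference,predicted Event tibbles (`event`, `time_s`), time-sorted.
#' @param max_gap_ms Maximum admissible timing gap for a match.
#' @return An `event_timing` object: list with `matches` (tibble of paired
#'   events with signed and absolute errors in ms), `summary` (per-kind `n`,
#'   `mae_ms`, `sd_ms`), `unmatched_reference`, `spurious_predicted`.
#' @export
match_events <- function(reference, predicted, max_gap_ms = 250) {
  stop_if_not_scalar_number(max_gap_ms, "max_gap_ms", positive = TRUE)
  match_kind <- function(kind) {
    rt <- sort(reference$time_s[reference$event == kind])
    pt <- sort(predicted$time_s[predicted$event == kind])
    if (length(rt) == 0 || length(pt) == 0) {
      return(list(
        matches = tibble::tibble(event = character(), ref_time_s = double(),
                                 pred_time_s = double(), error_ms = double(),
                                 abs_error_ms = double()),
        un_ref = length(rt), spur = length(pt)
      ))
    }
    gaps <- abs(outer(rt, pt, "-")) * 1000
    cand <- which(gaps <= max_gap_ms, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- cand[order(gaps[cand], cand[, 1]), , drop = FALSE]
    }
    used_r <- logical(length(rt))
    used_p <- logical(length(pt))
    pairs <- list()
    for (i in seq_len(nrow(cand))) {
      ri <- cand[i, 1]; pi <- cand[i, 2]
      if (!used_r[ri] && !used_p[pi]) {
        used_r[ri] <- TRUE
        used_p[pi] <- TRUE
        pairs[[length(pairs) + 1L]] <- c(ri, pi)
      }
    }
    m <- if (length(pairs) == 0) {
      tibble::tibble(event = character(), ref_time_s = double(),
                     pred_time_s = double(), error_ms = double(),
                     abs_error_ms = double())
    } else {
      ri <- purrr::map_int(pairs, ~ as.integer(.x[1]))
      pi <- purrr::map_int(pairs, ~ as.integer(.x[2]))
      tibble::tibble(
        event = kind,
        ref_time_s = rt[ri],
        pred_time_s = pt[pi],
        error_ms = (pt[pi] - rt[ri]) * 1000,
        abs_error_ms = abs(pt[pi] - rt[ri]) * 1000
      )
    }
    list(matches = dplyr::arrange(m, .data$ref_time_s),
         un_ref = sum(!used_r), spur = sum(!used_p))
  }

  kinds <- c("HS", "TO")
  res <- purrr::map(setNames(kinds, kinds), match_kind)
  matches <- dplyr::bind_rows(purrr::map(res, "matches"))
  summary <- purrr::map_dfr(kinds, function(k) {
    e <- matches$abs_error_ms[matches$event == k]
    tibble::tibble(
      event = k,
      n = length(e),
      mae_ms = if (length(e) > 0) mean(e) else NA_real_,
      sd_ms = if (length(e) > 1) sd(e) else NA_real_
    )
  })
  structure(
    list(
      matches = matches,
      summary = summary,
      unmatched_reference = sum(purrr::map_int(res, "un_ref")),
      spurious_predicted = sum(purrr::map_int(res, "spur"))
    ),
    class = "event_timing"
  )
}

#' @export
print.event_timing <- function(x, ...) {
  cat("<event_timing>\n")
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %s: n = %d, MAE = %s ms (SD %s)\n", s$event, s$n,
                formatC(s$mae_ms, digits = 2, format = "f"),
                formatC(s$sd_ms, digits = 2, format = "f")))
  }
  cat(sprintf("  unmatched reference: %d, spurious predicted: %d\n",
              x$unmatched_reference, x$spurious_predicted))
  invisible(x)
}

#' @export
tidy.event_timing <- function(x, ...) x$summary

#' @export
glance.event_timing <- function(x, ...) {
  tibble::tibble(
    n_matches = nrow(x$matches),
    mae_ms = mean(x$matches$abs_error_ms),
    unmatched_reference = x$unmatched_reference,
    spurious_predicted = x$spurious_predicted
  )
}

#' Detect events from a recording with a model
#'
#' Convenience composition of [predict_trace()], [binarize_trace()] and
#' [extract_events()]. The trace starts at sample `omega + 1`, and the
#' returned times are on the recording's clock.
#'
#' @param model A trained `gait_model` or [oracle_model()].
#' @param rec A preprocessed `gait_recording`.
#' @param threshold,min_phase_ms Passed to [binarize_trace()].
#' @return An event tibble (`event`, `time_s`).
#' @export
detect_events <- function(model, rec, threshold = 0.5, min_phase_ms = 100) {
  tr <- predict_trace(model, rec)
  b <- binarize_trace(tr$stance_prob, threshold = threshold,
                      min_phase_ms = min_phase_ms, fs_hz = rec$fs_hz)
  extract_events(b, fs_hz = rec$fs_hz, t0 = tr$time[1])
}
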