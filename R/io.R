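# Plain-text interchange: recording CSVs, event CSVs, cohort manifests.

#' Write / read a recording as CSV
#'
#' The on-disk schema is one row per sample with the header
#' `time,Ax,Ay,Az,Gx,Gy,Gz,Yaw,Pitch,Roll,stance`; the `stance` column is
#' omitted when the recording carries no reference trace, and channel columns
#' dropped by preprocessing are simply absent. True event times (sub-sample,
#' real-valued) do not survive the CSV round trip — only the sample-quantized
#' stance trace does — so `read_recording_csv()` reconstructs events from the
#' stance trace via [extract_events()].
#'
#' @param rec A `gait_recording`.
#' @param path File path to write to / read from.
#' @return `write_recording_csv()` returns `path` invisibly;
#'   `read_recording_csv()` returns a `gait_recording`.
#' @export
write_recording_csv <- function(rec, path) {
  assert_recording(rec)
  readr::write_csv(rec$signals, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param fs_hz Sampling rate of the stored recording.
#' @param meta Optional metadata list (`subject_id`, `age_group`,
#'   `speed_condition`, `task`).
#' @export
read_recording_csv <- function(path, fs_hz = 50, meta = list()) {
  sig <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"time" %in% names(sig)) abort("Recording CSV must have a `time` column.")
  events <- NULL
  if ("stance" %in% names(sig)) {
    events <- extract_events(sig$stance, fs_hz = fs_hz, t0 = sig$time[1])
  }
  structure(
    list(
      signals = tibble::as_tibble(sig),
      events = events,
      fs_hz = fs_hz,
      meta = modifyList(
        list(subject_id = NA_character_, age_group = NA_character_,
             speed_condition = NA_character_, task = NA_character_),
        meta
      ),
      profile = NULL
    ),
    class = "gait_recording"
  )
}

#' Write / read gait events as CSV
#'
#' Schema: `event_type,time_s` with `event_type` in `{"HS","TO"}`.
#'
#' @param events Tibble with columns `event` and `time_s`.
#' @param path File path.
#' @export
write_events_csv <- function(events, path) {
  readr::write_csv(
    dplyr::transmute(events, event_type = .data$event, time_s = .data$time_s),
    path, progress = FALSE
  )
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("event_type", "time_s") %in% names(x))) {
    abort("Events CSV must have columns `event_type` and `time_s`.")
  }
  tibble::tibble(event = x$event_type, time_s = x$time_s)
}

#' Write / read a cohort directory
#'
#' Writes one recording CSV and one events CSV per recording plus a JSON
#' manifest mapping each entry to its files and metadata.
#'
#' @param cohort A `gait_cohort`.
#' @param dir Output directory (created if missing).
#' @return `write_cohort()` returns the manifest path invisibly;
#'   `read_cohort()` returns a `gait_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- purrr::imap(cohort, function(r, i) {
    stem <- sprintf(
      "%s_%s_%s", r$meta$subject_id, r$meta$task, r$meta$speed_condition
    )
    rec_file <- paste0(stem, ".csv")
    ev_file <- paste0(stem, "_events.csv")
    write_recording_csv(r, file.path(dir, rec_file))
    if (!is.null(r$events)) write_events_csv(r$events, file.path(dir, ev_file))
    list(
      recording = rec_file,
      events = if (is.null(r$events)) NULL else ev_file,
      fs_hz = r$fs_hz,
      meta = r$meta
    )
  })
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest_path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(sprintf("No manifest.json found in `%s`.", dir))
  }
  entries <- jsonlite::read_json(manifest_path)
  recs <- purrr::map(entries, function(e) {
    read_recording_csv(
      file.path(dir, e$recording),
      fs_hz = e$fs_hz,
      meta = e$meta
    )
  })
  structure(recs, class = "gait_cohort")
}
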