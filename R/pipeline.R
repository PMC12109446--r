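# End-to-end pipeline: configuration, cohort-level helpers, evaluation,
# and the command-style entry points the inst/cli script delegates to.

#' Pipeline configuration
#'
#' One nested, serializable list driving the whole pipeline
#' (simulate -> preprocess -> window -> train -> evaluate -> parameters ->
#' compare). Every stage seed is derived from the single root `seed` via
#' named substreams, so one integer reproduces the full run.
#'
#' @param seed Root seed.
#' @param simulate,filter,windows,model,events,stride Per-stage overrides
#'   merged over the defaults (partial lists are fine).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, simulate = list(), filter = list(),
                            windows = list(), model = list(),
                            events = list(), stride = list()) {
  cfg <- list(
    seed = as.integer(seed),
    simulate = modifyList(list(
      n_subjects = 150L,
      speeds = c("normal", "low", "high"),
      tasks = "STW",
      cadence_range = c(90, 110),
      stance_fraction_range = c(0.58, 0.66),
      n_cycles = 6L,
      asymmetry = 0.02,
      noise_sd = 0.05,
      drift_sd = 0.002
    ), simulate),
    # kalman_q / kalman_r are only present when pinned to a number; absent
    # keys mean the data-scaled defaults (so the config serializes cleanly)
    filter = modifyList(list(
      lowpass_cutoff_hz = 10, lowpass_order = 4L,
      excluded_channels = DEFAULT_EXCLUDED
    ), filter),
    windows = modifyList(list(
      omega = 40L, fractions = c(0.6, 0.2, 0.2), unit = "by_subject"
    ), windows),
    model = modifyList(list(
      architecture = "bitcn_bigru_crossattn",
      tcn_channels = 64L, tcn_kernel = 3L, tcn_dilations = c(1L, 2L, 4L),
      gru_hidden = 64L, attn_heads = 4L, dropout = 0.2,
      lr = 1e-3, batch_size = 64L, epochs = 50L
    ), model),
    events = modifyList(list(
      threshold = 0.5, min_phase_ms = 100, max_gap_ms = 250
    ), events),
    stride = modifyList(list(
      intercept_m = 0.5, slope_m_per_hz = 0.85
    ), stride)
  )
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path File path; `.yaml`/`.yml` writes YAML, `.json` writes JSON.
#' @param config A `pipeline_config`.
#' @export
save_pipeline_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                         null = "null", digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_pipeline_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- pipeline_config(
    seed = x$seed %||% 1,
    simulate = x$simulate %||% list(),
    filter = x$filter %||% list(),
    windows = x$windows %||% list(),
    model = x$model %||% list(),
    events = x$events %||% list(),
    stride = x$stride %||% list()
  )
  cfg
}

as_filter_config <- function(f) {
  filter_config(
    kalman_q = f$kalman_q, kalman_r = f$kalman_r,
    lowpass_cutoff_hz = f$lowpass_cutoff_hz,
    lowpass_order = f$lowpass_order,
    excluded_channels = f$excluded_channels
  )
}

as_model_config <- function(m, seed = 1) {
  model_config(
    architecture = m$architecture,
    tcn_channels = m$tcn_channels, tcn_kernel = m$tcn_kernel,
    tcn_dilations = m$tcn_dilations, gru_hidden = m$gru_hidden,
    attn_heads = m$attn_heads, dropout = m$dropout, lr = m$lr,
    batch_size = m$batch_size, epochs = m$epochs, seed = seed
  )
}

#' Preprocess every recording of a cohort
#'
#' @param cohort A `gait_cohort` (or list of recordings).
#' @param config A [filter_config()].
#' @return The preprocessed `gait_cohort`.
#' @export
preprocess_cohort <- function(cohort, config = filter_config()) {
  structure(
    purrr::map(cohort, preprocess_recording, config = config),
    class = "gait_cohort"
  )
}

# Sample-quantized reference events, reconstructed from the binary stance
# trace exactly as an insole would deliver them.
reference_events <- function(rec) {
  extract_events(rec$signals$stance, fs_hz = rec$fs_hz,
                 t0 = rec$signals$time[1])
}

#' Evaluate event detection over a set of recordings
#'
#' Detects events on every recording with the model, matches them to the
#' recording's true events, and aggregates the timing MAE per event kind and
#' speed condition — the standard layout for reporting heel-strike /
#' toe-off errors across walking speeds.
#'
#' @param model A trained `gait_model` or [oracle_model()].
#' @param cohort Preprocessed recordings carrying `events` ground truth.
#' @param threshold,min_phase_ms,max_gap_ms Event-extraction and matching
#'   parameters (see [binarize_trace()], [match_events()]).
#' @return A `gait_evaluation`: list with `report` (tibble: `event`,
#'   `speed_condition`, `n`, `mae_ms`, `sd_ms`), `matches` (all matched
#'   pairs with metadata), `unmatched_reference`, `spurious_predicted`.
#' @export
evaluate_events <- function(model, cohort, threshold = 0.5,
                            min_phase_ms = 100, max_gap_ms = 250) {
  if (is_gait_recording(cohort)) cohort <- list(cohort)
  all_matches <- list()
  un_ref <- 0L
  spur <- 0L
  for (rec in cohort) {
    if (is.null(rec$events)) abort("Recording lacks ground-truth events.")
    pred <- detect_events(model, rec, threshold = threshold,
                          min_phase_ms = min_phase_ms)
    # Match over everything the trace covers, then score only events the
    # model can express: the first omega samples have no prediction, and
    # phases clipped below min_phase_ms by either trace edge are absorbed
    # by the debouncer, so a guard band at each edge is excluded.
    margin <- min_phase_ms / 1000
    trace_start <- rec$signals$time[1] + model$omega / rec$fs_hz
    t_min <- trace_start + margin
    t_max <- max(rec$signals$time) - margin
    ref <- rec$events[rec$events$time_s >= trace_start - 1 / rec$fs_hz, ]
    mt <- match_events(ref, pred, max_gap_ms = max_gap_ms)
    m <- mt$matches[mt$matches$ref_time_s >= t_min &
                      mt$matches$ref_time_s <= t_max, ]
    if (nrow(m) > 0) {
      m$subject_id <- rec$meta$subject_id %||% NA_character_
      m$speed_condition <- rec$meta$speed_condition %||% NA_character_
      m$task <- rec$meta$task %||% NA_character_
      all_matches[[length(all_matches) + 1L]] <- m
    }
    in_win <- function(t) t >= t_min & t <= t_max
    un_ref <- un_ref +
      sum(in_win(ref$time_s) & !ref$time_s %in% mt$matches$ref_time_s)
    spur <- spur +
      sum(in_win(pred$time_s) & !pred$time_s %in% mt$matches$pred_time_s)
  }
  matches <- dplyr::bind_rows(all_matches)
  report <- if (nrow(matches) == 0) {
    tibble::tibble(event = character(), speed_condition = character(),
                   n = integer(), mae_ms = double(), sd_ms = double())
  } else {
    dplyr::summarise(
      dplyr::group_by(matches, .data$event, .data$speed_condition),
      n = dplyr::n(),
      mae_ms = mean(.data$abs_error_ms),
      sd_ms = sd(.data$abs_error_ms),
      .groups = "drop"
    )
  }
  structure(
    list(report = report, matches = matches,
         unmatched_reference = un_ref, spurious_predicted = spur),
    class = "gait_evaluation"
  )
}

#' Write an event-timing evaluation as JSON
#'
#' Serializes the per-kind, per-speed MAE/SD table together with the match
#' and error counts.
#'
#' @param evaluation A `gait_evaluation`.
#' @param path Output JSON path.
#' @export
write_evaluation_json <- function(evaluation, path) {
  x <- list(
    report = evaluation$report,
    n_matches = nrow(evaluation$matches),
    unmatched_reference = evaluation$unmatched_reference,
    spurious_predicted = evaluation$spurious_predicted
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.gait_evaluation <- function(x, ...) {
  cat("<gait_evaluation>\n")
  print(x$report)
  cat(sprintf("  unmatched reference: %d, spurious predicted: %d\n",
              x$unmatched_reference, x$spurious_predicted))
  invisible(x)
}

#' @export
tidy.gait_evaluation <- function(x, ...) x$report

#' Gait parameters for every recording of a cohort
#'
#' @param cohort A `gait_cohort`.
#' @param model Optional model: when supplied, events are detected from the
#'   sensor channels; when `NULL`, the sample-quantized reference events
#'   (reconstructed from the stance trace) are used.
#' @param stride_model A `stride_length_model`.
#' @return A tibble, one row per recording (see [recording_parameters()]).
#' @export
cohort_parameters <- function(cohort, model = NULL,
                              stride_model = default_stride_model()) {
  purrr::map_dfr(cohort, function(rec) {
    ev <- if (is.null(model)) reference_events(rec) else {
      detect_events(model, rec)
    }
    recording_parameters(rec, events = ev, stride_model = stride_model)
  })
}

# Scaled-down model configuration used by the packaged experiments: small
# enough to train in minutes on one core, large enough to solve the
# synthetic benchmark.
scaled_model_config <- function(architecture = "bitcn_bigru_crossattn",
                                epochs = 10, seed = 1) {
  model_config(
    architecture = architecture,
    tcn_channels = 16, tcn_kernel = 3, tcn_dilations = c(1, 2, 4),
    gru_hidden = 16, attn_heads = 2, dropout = 0.1,
    lr = 3e-3, batch_size = 64, epochs = epochs, seed = seed
  )
}

#' Run the synthetic end-to-end experiment
#'
#' Simulates a cohort, preprocesses it, builds sliding-window pairs, splits
#' by subject, trains the requested architecture, and scores event timing
#' on the held-out test subjects. All randomness flows from `seed` through
#' named substreams (simulate / split / train).
#'
#' @param n_subjects Cohort size.
#' @param speeds,tasks Conditions recorded per subject.
#' @param omega Window length.
#' @param architecture Model architecture name (see [model_config()]).
#' @param epochs Training epochs.
#' @param model_cfg Optional full [model_config()] (overrides
#'   `architecture`/`epochs`; its seed is still replaced by the derived
#'   training seed).
#' @param filter_cfg A [filter_config()].
#' @param age_groups Age-band labels to stratify over; with few subjects per
#'   band the rounded per-band split can starve the test partition, so small
#'   experiments may prefer a single band.
#' @param seed Root seed.
#' @param verbose Print per-epoch losses.
#' @return A list: `model`, `evaluation` (a `gait_evaluation` on test
#'   subjects), `split`, `test_recordings`, `cohort`.
#' @export
run_gait_experiment <- function(n_subjects = 20,
                                speeds = "normal",
                                tasks = "STW",
                                omega = 40,
                                architecture = "bitcn_bigru_crossattn",
                                epochs = 10,
                                model_cfg = NULL,
                                filter_cfg = filter_config(),
                                age_groups = c("20-29", "30-39", "40-49",
                                               "50-59", "60-69", "70-79"),
                                seed = 1,
                                verbose = FALSE) {
  cohort <- simulate_cohort(
    n_subjects, speeds = speeds, tasks = tasks, age_groups = age_groups,
    seed = derive_seed(seed, "simulate")
  )
  pre <- preprocess_cohort(cohort, config = filter_cfg)
  pairs <- purrr::map(pre, make_pairs, omega = omega)
  split <- split_cohort(pairs, unit = "by_subject",
                        seed = derive_seed(seed, "split"))
  cfg <- model_cfg %||% scaled_model_config(architecture, epochs = epochs)
  cfg$seed <- derive_seed(seed, "train")
  model <- build_model(cfg, in_channels = dim(split$train$X)[3], omega = omega)
  model <- train_gait_model(model, split, epochs = epochs, verbose = verbose)
  test_subjects <- split$assignment$subject_id[split$assignment$partition == "test"]
  if (length(test_subjects) == 0) {
    abort(paste0(
      "The stratified split assigned no subjects to the test partition; ",
      "use more subjects per age band or fewer `age_groups`."
    ))
  }
  test_recs <- pre[purrr::map_lgl(pre, ~ .x$meta$subject_id %in% test_subjects)]
  evaluation <- evaluate_events(model, test_recs)
  list(model = model, evaluation = evaluation, split = split,
       test_recordings = test_recs, cohort = pre)
}

#' Run the synthetic dual-task comparison
#'
#' Simulates `n_subjects` walking under two tasks, measures the eight gait
#' parameters from the sample-quantized reference events of each trial, and
#' runs the paired per-parameter t tests.
#'
#' @param n_subjects Subjects (each completes both tasks).
#' @param tasks Length-2 character vector of task labels.
#' @param seed Root seed.
#' @param stride_model A `stride_length_model`.
#' @return A list: `parameters` (per-trial tibble), `comparison` (the
#'   [compare_tasks()] table).
#' @export
dual_task_experiment <- function(n_subjects = 25, tasks = c("STW", "VFT"),
                                 seed = 1,
                                 stride_model = default_stride_model()) {
  if (length(tasks) != 2) abort("`tasks` must name exactly two tasks.")
  cohort <- simulate_cohort(
    n_subjects, speeds = "normal", tasks = tasks,
    seed = derive_seed(seed, "simulate")
  )
  params <- cohort_parameters(cohort, stride_model = stride_model)
  comparison <- compare_tasks(params, task_a = tasks[1], task_b = tasks[2])
  list(parameters = params, comparison = comparison)
}

## ---- command-style entry points -------------------------------------------

#' Pipeline commands
#'
#' Thin command-style wrappers over the package's stages, used by the
#' bundled `gaitpipe` script (`system.file("cli", "gaitpipe.R", package =
#' "gaitevents")`). Each takes a [pipeline_config()] and file paths and
#' performs one stage.
#'
#' @param config A `pipeline_config`.
#' @param out_dir,data_dir,out_model,out_csv File locations.
#' @param n_subjects,epochs Optional overrides of the configured values.
#' @return `cmd_simulate()` the manifest path; `cmd_train()` the trained
#'   model (checkpoint + training-log CSV written to `out_model` and
#'   `<out_model>_log.csv`); `cmd_evaluate()` the per-kind, per-speed MAE
#'   report; `cmd_params()` the parameter tibble; `cmd_compare()` the
#'   comparison table.
#' @name pipeline_commands
NULL

#' @rdname pipeline_commands
#' @export
cmd_simulate <- function(config, out_dir, n_subjects = NULL) {
  s <- config$simulate
  cohort <- simulate_cohort(
    n_subjects %||% s$n_subjects,
    speeds = s$speeds, tasks = s$tasks,
    cadence_range = s$cadence_range,
    stance_fraction_range = s$stance_fraction_range,
    n_cycles = s$n_cycles, asymmetry = s$asymmetry,
    noise_sd = s$noise_sd, drift_sd = s$drift_sd,
    seed = derive_seed(config$seed, "simulate")
  )
  write_cohort(cohort, out_dir)
}

#' @rdname pipeline_commands
#' @export
cmd_train <- function(config, data_dir, out_model, epochs = NULL) {
  if (!dir.exists(data_dir)) {
    abort(sprintf("Data directory `%s` does not exist.", data_dir))
  }
  cohort <- read_cohort(data_dir)
  pre <- preprocess_cohort(cohort, as_filter_config(config$filter))
  pairs <- purrr::map(pre, make_pairs, omega = config$windows$omega)
  split <- split_cohort(pairs, fractions = config$windows$fractions,
                        unit = config$windows$unit,
                        seed = derive_seed(config$seed, "split"))
  cfg <- as_model_config(config$model, seed = derive_seed(config$seed, "train"))
  model <- build_model(cfg, in_channels = dim(split$train$X)[3],
                       omega = config$windows$omega)
  model <- train_gait_model(model, split, epochs = epochs)
  save_gait_model(model, out_model)
  readr::write_csv(model$history, paste0(out_model, "_log.csv"),
                   progress = FALSE)
  invisible(model)
}

#' @rdname pipeline_commands
#' @param model A trained `gait_model` or the path to a saved checkpoint.
#' @export
cmd_evaluate <- function(model, config, data_dir) {
  if (is.character(model)) model <- load_gait_model(model)
  if (!dir.exists(data_dir)) {
    abort(sprintf("Data directory `%s` does not exist.", data_dir))
  }
  cohort <- read_cohort(data_dir)
  pre <- preprocess_cohort(cohort, as_filter_config(config$filter))
  evaluate_events(
    model, pre,
    threshold = config$events$threshold,
    min_phase_ms = config$events$min_phase_ms,
    max_gap_ms = config$events$max_gap_ms
  )
}

#' @rdname pipeline_commands
#' @export
cmd_params <- function(config, data_dir, out_csv = NULL) {
  if (!dir.exists(data_dir)) {
    abort(sprintf("Data directory `%s` does not exist.", data_dir))
  }
  cohort <- read_cohort(data_dir)
  sm <- stride_length_model(config$stride$intercept_m,
                            config$stride$slope_m_per_hz)
  out <- cohort_parameters(cohort, stride_model = sm)
  if (!is.null(out_csv)) readr::write_csv(out, out_csv, progress = FALSE)
  out
}

#' @rdname pipeline_commands
#' @param params A parameter table (tibble) or the path to a parameters CSV.
#' @param task_a,task_b Tasks to contrast.
#' @export
cmd_compare <- function(params, task_a = "STW", task_b = "VFT") {
  if (is.character(params)) {
    params <- readr::read_csv(params, show_col_types = FALSE, progress = FALSE)
  }
  compare_tasks(params, task_a = task_a, task_b = task_b)
}
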