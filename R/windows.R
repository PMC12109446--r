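#' Build sliding-window input-output pairs
#'
#' Converts one preprocessed recording into supervised examples: pair `t`
#' (1-based) has input `X` = samples `t .. t + omega - 1` over the retained
#' channels and label `Y` = the stance reference at sample `t + omega`, i.e.
#' each window predicts the label of the sample immediately after it. The
#' first pair is samples `1..omega` predicting label `omega + 1`; the last is
#' samples `(n - omega)..(n - 1)` predicting label `n`; there are exactly
#' `n - omega` pairs. Windows never cross recording boundaries — pairs are
#' built per trial and pooled afterwards.
#'
#' @param rec A preprocessed `gait_recording` with a `stance` column.
#' @param omega Window length in samples (default 40, i.e. 0.8 s at 50 Hz).
#' @return A `window_pairs` object: list with `X` (array `n_pairs x omega x
#'   C`), `Y` (0/1 vector), `channels`, `omega`, `fs_hz`, `meta`, and
#'   `source` (tibble of subject id and window start index).
#' @examples
#' rec <- preprocess_recording(simulate_recording(gait_profile(seed = 1)))
#' pairs <- make_pairs(rec, omega = 40)
#' dim(pairs$X)
#' @export
make_pairs <- function(rec, omega = 40) {
  assert_recording(rec)
  stop_if_not_scalar_number(omega, "omega", positive = TRUE)
  omega <- as.integer(omega)
  if (!"stance" %in% names(rec$signals)) {
    abort("Recording has no `stance` reference; labels cannot be built.")
  }
  n <- nrow(rec$signals)
  if (n <= omega) {
    abort(sprintf("Recording length (%d) must exceed the window length (%d).", n, omega))
  }
  chans <- recording_channels(rec)
  M <- as.matrix(rec$signals[, chans])
  np <- n - omega
  X <- array(0, dim = c(np, omega, length(chans)),
             dimnames = list(NULL, NULL, chans))
  for (j in seq_len(omega)) {
    X[, j, ] <- M[j:(j + np - 1), , drop = FALSE]
  }
  structure(
    list(
      X = X,
      Y = as.numeric(rec$signals$stance[(omega + 1):n]),
      channels = chans,
      omega = omega,
      fs_hz = rec$fs_hz,
      meta = rec$meta,
      source = tibble::tibble(
        subject_id = rec$meta$subject_id %||% NA_character_,
        age_group = rec$meta$age_group %||% NA_character_,
        speed_condition = rec$meta$speed_condition %||% NA_character_,
        task = rec$meta$task %||% NA_character_,
        start = seq_len(np)
      )
    ),
    class = "window_pairs"
  )
}

#' @export
print.window_pairs <- function(x, ...) {
  cat(sprintf(
    "<window_pairs> %d pairs | omega = %d | %d channels (%s)\n",
    length(x$Y), x$omega, length(x$channels), paste(x$channels, collapse = ", ")
  ))
  invisible(x)
}

# Concatenate a list of window_pairs objects (same omega/channels) into one.
bind_pairs <- function(pairs_list) {
  pairs_list <- pairs_list[purrr::map_int(pairs_list, ~ length(.x$Y)) > 0]
  if (length(pairs_list) == 0) {
    abort("No window pairs to combine.")
  }
  omega <- pairs_list[[1]]$omega
  chans <- pairs_list[[1]]$channels
  for (p in pairs_list) {
    if (p$omega != omega || !identical(p$channels, chans)) {
      abort("All window sets must share omega and channels.")
    }
  }
  ns <- purrr::map_int(pairs_list, ~ length(.x$Y))
  total <- sum(ns)
  X <- array(0, dim = c(total, omega, length(chans)),
             dimnames = list(NULL, NULL, chans))
  at <- 0L
  for (p in pairs_list) {
    idx <- at + seq_len(length(p$Y))
    X[idx, , ] <- p$X
    at <- at + length(p$Y)
  }
  structure(
    list(
      X = X,
      Y = unlist(purrr::map(pairs_list, "Y"), use.names = FALSE),
      channels = chans,
      omega = omega,
      fs_hz = pairs_list[[1]]$fs_hz,
      meta = list(),
      source = dplyr::bind_rows(purrr::map(pairs_list, "source"))
    ),
    class = "window_pairs"
  )
}

# Largest-remainder allocation of `n` items to fractions `f` (sums to n).
largest_remainder <- function(n, f) {
  raw <- n * f
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_by <- order(raw - base, decreasing = TRUE)
    base[order_by[seq_len(rem)]] <- base[order_by[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Split window pairs into train / validation / test sets
#'
#' Splits are stratified within age group. With `unit = "by_subject"`
#' (the default) whole subjects are assigned to one partition, which
#' prevents leakage of a subject's windows across partitions; with
#' `unit = "by_pair"` individual pairs are allocated, mirroring a reading in
#' which the pool of pairs itself is divided. Counts use largest-remainder
#' rounding; the assignment is deterministic under `seed`.
#'
#' @param pairs_list A list of `window_pairs`, one per recording.
#' @param fractions Numeric triple summing to 1 (default `c(0.6, 0.2, 0.2)`).
#' @param unit `"by_subject"` or `"by_pair"`.
#' @param seed Integer seed for the shuffling.
#' @return A `dataset_split`: list with `train`, `val`, `test`
#'   (`window_pairs`), the `assignment` tibble, `fractions` and `unit`.
#' @export
split_cohort <- function(pairs_list,
                         fractions = c(0.6, 0.2, 0.2),
                         unit = c("by_subject", "by_pair"),
                         seed = 1) {
  unit <- match.arg(unit)
  if (inherits(pairs_list, "window_pairs")) pairs_list <- list(pairs_list)
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8) {
    abort("`fractions` must be three numbers summing to 1.")
  }
  parts <- c("train", "val", "test")
  info <- purrr::map_dfr(seq_along(pairs_list), function(i) {
    tibble::tibble(
      idx = i,
      subject_id = pairs_list[[i]]$meta$subject_id %||% sprintf("rec%03d", i),
      age_group = (pairs_list[[i]]$meta$age_group %||% NA_character_)
    )
  })
  info$age_group[is.na(info$age_group)] <- "(all)"

  if (unit == "by_subject") {
    assignment <- with_local_seed(seed, {
      purrr::map_dfr(split(info, info$age_group), function(g) {
        subjects <- sort(unique(g$subject_id))
        subjects <- sample(subjects)
        counts <- largest_remainder(length(subjects), fractions)
        tibble::tibble(
          subject_id = subjects,
          age_group = g$age_group[1],
          partition = rep(parts, times = counts)
        )
      })
    })
    get_part <- function(part) {
      subs <- assignment$subject_id[assignment$partition == part]
      sel <- info$idx[info$subject_id %in% subs]
      if (length(sel) == 0) NULL else bind_pairs(pairs_list[sel])
    }
    out <- purrr::map(setNames(parts, parts), get_part)
  } else {
    all_pairs <- bind_pairs(pairs_list)
    grp <- all_pairs$source$age_group
    grp[is.na(grp)] <- "(all)"
    part_of <- character(length(all_pairs$Y))
    with_local_seed(seed, {
      for (g in unique(grp)) {
        idx <- which(grp == g)
        idx <- sample(idx)
        counts <- largest_remainder(length(idx), fractions)
        part_of[idx] <- rep(parts, times = counts)
      }
    })
    take <- function(part) {
      sel <- which(part_of == part)
      if (length(sel) == 0) return(NULL)
      structure(
        list(
          X = all_pairs$X[sel, , , drop = FALSE],
          Y = all_pairs$Y[sel],
          channels = all_pairs$channels,
          omega = all_pairs$omega,
          fs_hz = all_pairs$fs_hz,
          meta = list(),
          source = all_pairs$source[sel, ]
        ),
        class = "window_pairs"
      )
    }
    out <- purrr::map(setNames(parts, parts), take)
    assignment <- dplyr::count(
      tibble::tibble(partition = part_of, age_group = grp),
      .data$age_group, .data$partition
    )
  }

  structure(
    list(
      train = out$train, val = out$val, test = out$test,
      assignment = assignment, fractions = fractions, unit = unit
    ),
    class = "dataset_split"
  )
}

#' Write a split manifest as JSON
#'
#' Records which subjects (or, for pair-level splits, how many pairs per
#' age group) landed in each partition, so a split can be audited and
#' reproduced.
#'
#' @param split A `dataset_split`.
#' @param path Output JSON path.
#' @export
write_split_manifest <- function(split, path) {
  x <- list(
    unit = split$unit,
    fractions = split$fractions,
    assignment = split$assignment
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.dataset_split <- function(x, ...) {
  sizes <- purrr::map_int(x[c("train", "val", "test")],
                          ~ if (is.null(.x)) 0L else length(.x$Y))
  cat(sprintf(
    "<dataset_split> unit = %s | train %d / val %d / test %d pairs\n",
    x$unit, sizes[1], sizes[2], sizes[3]
  ))
  invisible(x)
}
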