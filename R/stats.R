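#' Paired t test for one gait parameter
#'
#' Two-sided paired t test on per-subject means under two walking tasks,
#' flagged for significance at 0.05. Degenerate inputs are handled by a
#' documented convention rather than an error: when every within-subject
#' difference is identical, the t statistic is undefined, so the test
#' returns `t = 0, p = 1` if the common difference is zero and
#' `t = +/-Inf, p = 0` otherwise (a constant nonzero shift across all
#' subjects is treated as maximal evidence of a difference).
#'
#' @param values_a,values_b Equal-length numeric vectors, one entry per
#'   subject, same subject order.
#' @param parameter Optional parameter label carried into the output.
#' @return A one-row tibble: `parameter`, `n`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`, `mean_diff`, `t`, `p`, `significant`.
#' @examples
#' paired_ttest(c(1.1, 1.2, 1.3), c(1.0, 1.05, 1.2))
#' @export
paired_ttest <- function(values_a, values_b, parameter = NA_character_) {
  if (length(values_a) != length(values_b)) {
    abort("`values_a` and `values_b` must have the same length (paired).")
  }
  n <- length(values_a)
  if (n < 2) abort("Need at least two pairs.")
  d <- values_a - values_b
  # differences constant up to floating-point noise leave the t statistic
  # undefined; apply the documented degenerate-case convention
  if (sd(d) <= 1e-12 * (abs(mean(d)) + .Machine$double.xmin)) {
    if (mean(d) == 0) {
      tstat <- 0; pval <- 1
    } else {
      tstat <- sign(mean(d)) * Inf; pval <- 0
    }
  } else {
    tt <- t.test(values_a, values_b, paired = TRUE)
    tstat <- unname(tt$statistic)
    pval <- tt$p.value
  }
  tibble::tibble(
    parameter = parameter,
    n = n,
    mean_a = mean(values_a), sd_a = sd(values_a),
    mean_b = mean(values_b), sd_b = sd(values_b),
    mean_diff = mean(d),
    t = tstat,
    p = pval,
    significant = pval < 0.05
  )
}

#' Compare gait parameters between two walking tasks
#'
#' Runs the paired t test of [paired_ttest()] for each of the eight gait
#' parameters across subjects that completed both tasks. Tests are
#' uncorrected by default, matching the conventional presentation of eight
#' per-parameter contrasts; `adjust = "holm"` applies a Holm correction to
#' the eight p values instead.
#'
#' @param params_df A parameter table with one row per subject x task —
#'   e.g. rows from [recording_parameters()] bound together.
#' @param task_a,task_b Task labels to contrast (a positive `mean_diff`
#'   means `task_a` larger).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A `task_comparison` tibble: one row per parameter with the
#'   [paired_ttest()] columns plus `task_a`/`task_b`.
#' @export
compare_tasks <- function(params_df, task_a = "STW", task_b = "VFT",
                          adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  cols <- c("cadence_spm", "stride_time_s", "stance_phase_pct",
            "swing_phase_pct", "stance_time_s", "swing_time_s",
            "stride_length_m", "walking_speed_mps")
  need <- c("subject_id", "task", cols)
  if (!all(need %in% names(params_df))) {
    abort(sprintf("`params_df` is missing columns: %s.",
                  paste(setdiff(need, names(params_df)), collapse = ", ")))
  }
  a <- params_df[params_df$task == task_a, ]
  b <- params_df[params_df$task == task_b, ]
  common <- intersect(a$subject_id, b$subject_id)
  if (length(common) < 2) {
    abort("Need at least two subjects with both tasks.")
  }
  a <- a[match(common, a$subject_id), ]
  b <- b[match(common, b$subject_id), ]
  out <- purrr::map_dfr(cols, function(cc) {
    paired_ttest(a[[cc]], b[[cc]], parameter = cc)
  })
  if (adjust == "holm") {
    out$p <- p.adjust(out$p, method = "holm")
    out$significant <- out$p < 0.05
  }
  out <- dplyr::mutate(out, task_a = task_a, task_b = task_b,
                       .before = "parameter")
  class(out) <- c("task_comparison", class(out))
  out
}

#' Bland-Altman agreement summary
#'
#' Summarizes agreement between detected and reference event times (or any
#' paired measurements): the bias is the mean signed difference
#' `detected - reference`, and the limits of agreement are
#' `bias +/- 1.96 * SD` of the differences. With a grouping vector (e.g.
#' speed condition), per-group rows are reported alongside the pooled row.
#'
#' @param detected,reference Equal-length numeric vectors of matched values
#'   (seconds for event times; the summary itself is unit-agnostic).
#' @param group Optional grouping vector, same length.
#' @return A `bland_altman` tibble: `group`, `n`, `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`; the paired means/differences are attached as
#'   the `"data"` attribute for plotting.
#' @examples
#' bland_altman(c(1.02, 2.01, 2.98), c(1.00, 2.00, 3.00))
#' @export
bland_altman <- function(detected, reference, group = NULL) {
  if (length(detected) != length(reference)) {
    abort("`detected` and `reference` must have the same length.")
  }
  if (length(detected) < 2) abort("Need at least two pairs.")
  d <- detected - reference
  m <- (detected + reference) / 2
  grp <- if (is.null(group)) rep("(pooled)", length(d)) else as.character(group)
  summarise_one <- function(dd, label) {
    tibble::tibble(
      group = label,
      n = length(dd),
      bias = mean(dd),
      sd_diff = sd(dd),
      loa_lower = mean(dd) - 1.96 * sd(dd),
      loa_upper = mean(dd) + 1.96 * sd(dd)
    )
  }
  out <- purrr::map_dfr(unique(grp), ~ summarise_one(d[grp == .x], .x))
  if (!is.null(group)) {
    out <- dplyr::bind_rows(out, summarise_one(d, "(pooled)"))
  }
  attr(out, "data") <- tibble::tibble(mean = m, diff = d, group = grp)
  class(out) <- c("bland_altman", class(out))
  out
}
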