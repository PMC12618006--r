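#' Bin cytokinesis events into fixed-width time bins
#'
#' Counts events in half-open bins `[k*bin_h, (k+1)*bin_h)` covering the
#' observation span; an event falling exactly on the span end is assigned
#' to the final bin. Total counts are conserved for every bin width.
#'
#' @param record A [mitosis_record()].
#' @param bin_h Bin width in hours (default 1.5 h).
#' @return Tibble with `bin_start_h`, `bin_end_h`, `count`.
#' @export
bin_mitoses <- function(record, bin_h = 1.5) {
  stopifnot(inherits(record, "mitosis_record"), bin_h > 0)
  span <- record$observation_span_h
  t <- record$event_times_h
  if (length(t) && (any(t < 0) || any(t > span))) {
    stop(sprintf(
      "event(s) outside observation span [0, %g]: %s", span,
      paste(utils::head(t[t < 0 | t > span], 5), collapse = ", ")
    ), call. = FALSE)
  }
  n_bins <- ceiling(span / bin_h)
  idx <- pmin(floor(t / bin_h) + 1L, n_bins) # span-end events into last bin
  counts <- tabulate(idx, nbins = n_bins)
  tibble::tibble(
    bin_start_h = (seq_len(n_bins) - 1) * bin_h,
    bin_end_h = pmin(seq_len(n_bins) * bin_h, span),
    count = counts
  )
}

#' Normalize a binned mitosis time course to a control's first bin
#'
#' Each bin count is divided by the first-bin count of the matching
#' low-K+ control from the same experiment, so time courses from
#' experiments with different cell numbers are comparable.
#'
#' @param counts Binned counts: output of [bin_mitoses()] or a numeric
#'   vector.
#' @param control_counts The control condition's binned counts (same
#'   experiment), in either form; only its first bin is used.
#' @return `counts` with a `normalized` column (or a numeric vector when
#'   `counts` is one).
#' @export
normalize_timecourse <- function(counts, control_counts) {
  first_bin <- if (is.data.frame(control_counts)) {
    control_counts$count[1]
  } else {
    control_counts[1]
  }
  if (!is.finite(first_bin) || first_bin <= 0) {
    stop(paste(
      "control first-bin count is zero;",
      "pool bins or exclude this experiment before normalizing"
    ), call. = FALSE)
  }
  if (is.data.frame(counts)) {
    counts$normalized <- counts$count / first_bin
    counts
  } else {
    counts / first_bin
  }
}

#' Accumulated mitotic activity ratios and condition contrasts
#'
#' For each experiment, accumulates event counts over the first
#' `window_h` hours per condition and expresses each treated condition as
#' a ratio to the same experiment's control condition. Per condition, the
#' ratios are then tested against 1 with a one-sample t-test. Experiments
#' lacking a control arm are skipped with a warning.
#'
#' @param events Tibble with `experiment_id`, `condition`, `event_time_h`
#'   (one row per event), or a list of [mitosis_record()]s.
#' @param window_h Accumulation window (default 6 h).
#' @param control Control condition label (default `"5K"`).
#' @param conditions Optional declared condition set; labels outside it
#'   are an error.
#' @return List with `ratios` (tibble `experiment_id`, `condition`,
#'   `events`, `control_events`, `ratio`) and `contrasts` (tibble
#'   `condition`, `n`, `mean_ratio`, `statistic`, `df`, `p_value` from the
#'   one-sample test vs 1).
#' @seealso [paired_condition_contrast()] for within-experiment pairs of
#'   treated arms.
#' @export
accumulate_and_contrast <- function(events, window_h = 6, control = "5K",
                                    conditions = NULL) {
  if (is.list(events) && !is.data.frame(events) &&
    all(vapply(events, inherits, logical(1), "mitosis_record"))) {
    events <- dplyr::bind_rows(lapply(events, function(r) {
      tibble::tibble(
        experiment_id = r$experiment_id, condition = r$condition,
        event_time_h = r$event_times_h
      )
    }))
  }
  stopifnot(all(c("experiment_id", "condition", "event_time_h") %in% names(events)))
  if (!is.null(conditions)) {
    bad <- setdiff(unique(events$condition), conditions)
    if (length(bad)) {
      stop(sprintf(
        "condition label(s) not in the declared set: %s",
        paste(bad, collapse = ", ")
      ), call. = FALSE)
    }
  }
  acc <- events |>
    dplyr::filter(.data$event_time_h >= 0, .data$event_time_h < window_h) |>
    dplyr::count(.data$experiment_id, .data$condition, name = "events")
  ctrl <- acc |>
    dplyr::filter(.data$condition == control) |>
    dplyr::select("experiment_id", control_events = "events")
  missing_ctrl <- setdiff(unique(acc$experiment_id), ctrl$experiment_id)
  if (length(missing_ctrl)) {
    warning(sprintf(
      "experiment(s) without a %s control skipped: %s",
      control, paste(missing_ctrl, collapse = ", ")
    ), call. = FALSE)
  }
  ratios <- acc |>
    dplyr::filter(.data$condition != control) |>
    dplyr::inner_join(ctrl, by = "experiment_id") |>
    dplyr::mutate(ratio = .data$events / .data$control_events)
  contrasts <- ratios |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_ratio = mean(.data$ratio),
      statistic = if (dplyr::n() >= 2 && stats::sd(.data$ratio) > 0) {
        unname(stats::t.test(.data$ratio, mu = 1)$statistic)
      } else {
        NA_real_
      },
      df = if (dplyr::n() >= 2 && stats::sd(.data$ratio) > 0) {
        dplyr::n() - 1
      } else {
        NA_real_
      },
      p_value = if (dplyr::n() >= 2 && stats::sd(.data$ratio) > 0) {
        stats::t.test(.data$ratio, mu = 1)$p.value
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  list(ratios = ratios, contrasts = contrasts)
}

#' Paired contrast between two treated conditions
#'
#' Paired t-test on the per-experiment accumulated ratios of two
#' conditions, matched by `experiment_id` (e.g. a depolarizing condition
#' with and without a MEK inhibitor).
#'
#' @param ratios The `ratios` tibble from [accumulate_and_contrast()].
#' @param cond_a,cond_b Condition labels to compare.
#' @return List with `n`, `mean_difference` (a - b), `statistic`, `df`,
#'   `p_value`.
#' @export
paired_condition_contrast <- function(ratios, cond_a, cond_b) {
  wide <- ratios |>
    dplyr::filter(.data$condition %in% c(cond_a, cond_b)) |>
    dplyr::select("experiment_id", "condition", "ratio") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "ratio") |>
    tidyr::drop_na()
  if (nrow(wide) < 2L) {
    stop("fewer than two experiments have both conditions", call. = FALSE)
  }
  tt <- stats::t.test(wide[[cond_a]], wide[[cond_b]], paired = TRUE)
  list(
    n = nrow(wide),
    mean_difference = mean(wide[[cond_a]] - wide[[cond_b]]),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value
  )
}
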