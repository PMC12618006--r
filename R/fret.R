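`%||%` <- function(a, b) if (is.null(a)) b else a

.meta_cols <- c("dish_id", "k_out", "condition", "voltage_mV")

#' Compute the raw YFP/CFP ratio of each trace
#'
#' @param traces Tibble with `cell_id`, `time_min`, `cfp`, `yfp` (e.g. from
#'   [extract_cell_traces()] or a simulated `trace_set`'s `traces`).
#' @return The input with a `ratio` column appended.
#' @export
compute_ratio <- function(traces) {
  if (inherits(traces, "trace_set")) traces <- traces$traces
  stopifnot(all(c("cell_id", "time_min", "cfp", "yfp") %in% names(traces)))
  bad <- traces$cfp <= 0 | !is.finite(traces$cfp)
  if (any(bad)) {
    off <- traces[bad, c("cell_id", "time_min")]
    stop(sprintf(
      "non-positive CFP at %d timepoint(s): %s",
      sum(bad),
      paste(utils::head(sprintf("%s@%g", off$cell_id, off$time_min), 5), collapse = ", ")
    ), call. = FALSE)
  }
  dplyr::mutate(traces, ratio = .data$yfp / .data$cfp)
}

#' Normalize ratio traces to a per-cell reference window
#'
#' Divides each cell's ratio by the mean of its own ratio over the
#' reference window (half-open `[start, end)`), taken before the stimulus.
#' This removes dish-to-dish differences in probe expression and optical
#' gain; by construction the mean of the normalized ratio over the window
#' is 1.
#'
#' @param ratio_traces Output of [compute_ratio()].
#' @param reference_window `c(start, end)` in minutes; needs at least two
#'   timepoints per cell inside the window.
#' @return The input with `norm_ratio` and `reference` columns appended.
#' @export
normalize_traces <- function(ratio_traces, reference_window) {
  stopifnot(
    all(c("cell_id", "time_min", "ratio") %in% names(ratio_traces)),
    length(reference_window) == 2, reference_window[1] < reference_window[2]
  )
  w1 <- reference_window[1]
  w2 <- reference_window[2]
  out <- ratio_traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::mutate(
      .n_in = sum(.data$time_min >= w1 & .data$time_min < w2),
      reference = mean(.data$ratio[.data$time_min >= w1 & .data$time_min < w2]),
      norm_ratio = .data$ratio / .data$reference
    ) |>
    dplyr::ungroup()
  if (any(out$.n_in < 2L)) {
    bad <- unique(out$cell_id[out$.n_in < 2L])
    stop(sprintf(
      "reference window [%g, %g) contains fewer than 2 timepoints for cell(s): %s",
      w1, w2, paste(utils::head(bad, 5), collapse = ", ")
    ), call. = FALSE)
  }
  dplyr::select(out, -".n_in")
}

.summarise_meta <- function(grouped_df) {
  present <- intersect(.meta_cols, names(grouped_df))
  lapply(
    stats::setNames(present, present),
    function(col) rlang::expr(dplyr::first(.data[[!!col]]))
  )
}

#' Per-cell % ERK activity
#'
#' The paper's single-cell statistic: the stimulus-phase maximum of the
#' normalized YFP/CFP ratio, expressed as a percentage of the EGF-phase
#' maximum, both after subtracting the mean normalized ratio over the
#' baseline window:
#' `100 * (stim_max - baseline) / (egf_max - baseline)`.
#' With `subtract_baseline = FALSE` the plain ratio of maxima
#' `100 * stim_max / egf_max` is returned instead.
#'
#' @param norm_traces Output of [normalize_traces()].
#' @param protocol The [perfusion_protocol()] the traces were acquired
#'   under; must contain `stimulus` and `egf` phases.
#' @param baseline_window Half-open window for the baseline mean; default
#'   the final 2 min of the baseline phase (the 8-10 min convention for a
#'   10-min baseline).
#' @param subtract_baseline Use the baseline-subtracted form (default).
#' @param stim_lag_min Extend the stimulus search window by this many
#'   minutes past the phase end (default 0).
#' @return Tibble with one row per cell: `cell_id`, metadata columns when
#'   present (`dish_id`, `k_out`, ...), `baseline`, `stim_max`, `egf_max`,
#'   `percent_erk`. Cells whose EGF maximum does not exceed baseline get
#'   `percent_erk = NA` (routed to exclusion downstream).
#' @export
percent_erk <- function(norm_traces, protocol, baseline_window = NULL,
                        subtract_baseline = TRUE, stim_lag_min = 0) {
  stopifnot(
    inherits(protocol, "perfusion_protocol"),
    all(c("cell_id", "time_min", "norm_ratio") %in% names(norm_traces))
  )
  ph <- protocol$phases
  if (!all(c("stimulus", "egf") %in% ph$role)) {
    stop("protocol must contain stimulus and egf phases", call. = FALSE)
  }
  if (is.null(baseline_window)) baseline_window <- .default_baseline_window(protocol)
  stim <- ph[ph$role == "stimulus", ][1, ]
  egf <- ph[ph$role == "egf", ][1, ]
  w1 <- baseline_window[1]
  w2 <- baseline_window[2]
  s1 <- stim$start_min
  s2 <- stim$end_min + stim_lag_min
  e1 <- egf$start_min
  e2 <- egf$end_min
  meta <- .summarise_meta(norm_traces)
  out <- norm_traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      !!!meta,
      baseline = mean(.data$norm_ratio[.data$time_min >= w1 & .data$time_min < w2]),
      stim_max = max(.data$norm_ratio[.data$time_min >= s1 & .data$time_min < s2]),
      egf_max = max(.data$norm_ratio[.data$time_min >= e1 & .data$time_min < e2]),
      .groups = "drop"
    )
  if (subtract_baseline) {
    out$percent_erk <- ifelse(out$egf_max > out$baseline,
      100 * (out$stim_max - out$baseline) / (out$egf_max - out$baseline),
      NA_real_
    )
  } else {
    out$percent_erk <- ifelse(out$egf_max > 0, 100 * out$stim_max / out$egf_max, NA_real_)
  }
  out
}

#' Exclude cells that did not respond to EGF
#'
#' Implements the dead/unhealthy-cell exclusion rule as an explicit
#' criterion: a cell is excluded when its EGF response
#' `egf_max - baseline` is smaller than `k_sigma` times the SD of its
#' normalized ratio over the baseline phase (i.e. the response is not
#' distinguishable from baseline noise), or when its `percent_erk` is
#' undefined. An empty included set is a valid outcome and is reported
#' with a warning.
#'
#' @param responses Output of [percent_erk()].
#' @param norm_traces The [normalize_traces()] output the responses came
#'   from (used to estimate baseline noise).
#' @param protocol The acquisition [perfusion_protocol()].
#' @param k_sigma Threshold multiplier (default 3).
#' @return `responses` with `sd_baseline`, `included`, `reason` columns.
#' @export
exclude_nonresponders <- function(responses, norm_traces, protocol, k_sigma = 3) {
  stopifnot(inherits(protocol, "perfusion_protocol"), k_sigma > 0)
  ph <- protocol$phases
  b <- ph[ph$role == "baseline", ][1, ]
  noise <- norm_traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      sd_baseline = stats::sd(.data$norm_ratio[
        .data$time_min >= b$start_min & .data$time_min < b$end_min
      ]),
      .groups = "drop"
    )
  out <- dplyr::left_join(responses, noise, by = "cell_id")
  no_egf <- !is.finite(out$percent_erk)
  weak <- (out$egf_max - out$baseline) < k_sigma * out$sd_baseline
  out$included <- !(no_egf | weak)
  out$reason <- dplyr::case_when(
    no_egf ~ "EGF maximum not above baseline",
    weak ~ sprintf("EGF response below %g x baseline SD", k_sigma),
    TRUE ~ NA_character_
  )
  if (!any(out$included)) {
    warning("no cells passed the EGF-response criterion; included set is empty",
      call. = FALSE
    )
  }
  out
}

#' Phase-wise summaries of a normalized trace
#'
#' The four per-cell quantities plotted for clamp experiments: baseline
#' mean, depolarized-phase (stimulus) maximum, repolarized-phase minimum,
#' and EGF-phase maximum of the normalized ratio.
#'
#' @param norm_traces Output of [normalize_traces()].
#' @param protocol The acquisition [perfusion_protocol()].
#' @param roles Roles to summarise; defaults to all four. Every requested
#'   role must exist in the protocol.
#' @return Tibble with one row per cell and one column per requested
#'   summary (`baseline_mean`, `stimulus_max`, `repolarized_min`,
#'   `egf_max`).
#' @export
phase_extrema <- function(norm_traces, protocol,
                          roles = c("baseline", "stimulus", "repolarized", "egf")) {
  stopifnot(inherits(protocol, "perfusion_protocol"))
  ph <- protocol$phases
  missing_roles <- setdiff(roles, ph$role)
  if (length(missing_roles)) {
    stop(sprintf(
      "protocol has no phase with role: %s",
      paste(missing_roles, collapse = ", ")
    ), call. = FALSE)
  }
  stat_for <- c(
    baseline = "mean", stimulus = "max", repolarized = "min", egf = "max"
  )
  exprs <- list()
  for (r in roles) {
    p <- ph[ph$role == r, ][1, ]
    fn <- stat_for[[r]]
    nm <- paste0(r, "_", fn)
    exprs[[nm]] <- rlang::expr(
      (!!rlang::sym(fn))(.data$norm_ratio[
        .data$time_min >= !!p$start_min & .data$time_min < !!p$end_min
      ])
    )
  }
  meta <- .summarise_meta(norm_traces)
  norm_traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(!!!meta, !!!exprs, .groups = "drop")
}

#' Quantify a trace set end to end
#'
#' Convenience wrapper: ratio, reference normalization, %ERK, and the
#' EGF-response exclusion, using the trace set's own protocol and baseline
#' window.
#'
#' @param traceset A `trace_set` from [simulate_population()] or
#'   [simulate_conditions()], or a list with `traces` and `protocol`.
#' @param baseline_window Optional override of the reference window.
#' @param k_sigma Exclusion threshold, see [exclude_nonresponders()].
#' @param subtract_baseline See [percent_erk()].
#' @return List with `norm_traces` and `responses` (the excluded flag
#'   included).
#' @export
quantify_traceset <- function(traceset, baseline_window = NULL, k_sigma = 3,
                              subtract_baseline = TRUE) {
  stopifnot(!is.null(traceset$traces), !is.null(traceset$protocol))
  protocol <- traceset$protocol
  if (is.null(baseline_window)) {
    baseline_window <- traceset$baseline_window %||% .default_baseline_window(protocol)
  }
  norm <- traceset$traces |>
    compute_ratio() |>
    normalize_traces(baseline_window)
  resp <- percent_erk(norm, protocol,
    baseline_window = baseline_window,
    subtract_baseline = subtract_baseline
  )
  resp <- exclude_nonresponders(resp, norm, protocol, k_sigma = k_sigma)
  list(norm_traces = norm, responses = resp)
}
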