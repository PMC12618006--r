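.write_report_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Assemble a report of figures and their backing tables
#'
#' Writes a deterministic set of CSV tables and, for each table, a figure,
#' for whichever stage outputs are supplied; absent stages are simply
#' omitted. Every figure is backed by a CSV of exactly the numbers it
#' plots, and each summary CSV records the error-bar convention it uses
#' (`sem` for perfusion-style mean traces and %ERK panels, `sd` for
#' clamp-style traces).
#'
#' @param out_dir Output directory (created if needed).
#' @param responses Optional [percent_erk()] output (ideally after
#'   [exclude_nonresponders()]); plotted as %ERK distributions by
#'   condition.
#' @param norm_traces Optional [normalize_traces()] output; plotted as
#'   mean +/- error normalized-ratio time courses by condition.
#' @param correlation Optional [correlate_erk()] result; plotted as the
#'   per-cell scatter with the linear fit and its 95% confidence band.
#' @param mitosis Optional list from [accumulate_and_contrast()].
#' @param lifetimes Optional [normalize_lifetime()] output.
#' @param trace_error `"sem"` or `"sd"` for the trace panel.
#' @return Invisibly, the vector of files written.
#' @export
build_report <- function(out_dir, responses = NULL, norm_traces = NULL,
                         correlation = NULL, mitosis = NULL, lifetimes = NULL,
                         trace_error = c("sem", "sd")) {
  trace_error <- match.arg(trace_error)
  if (is.null(responses) && is.null(norm_traces) && is.null(correlation) &&
    is.null(mitosis) && is.null(lifetimes)) {
    stop("at least one stage output must be supplied", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  cond_col <- function(df) {
    for (c in c("condition", "k_out", "voltage_mV")) {
      if (c %in% names(df)) {
        return(c)
      }
    }
    NULL
  }

  if (!is.null(norm_traces)) {
    cc <- cond_col(norm_traces) %||% "condition"
    if (!cc %in% names(norm_traces)) norm_traces[[cc]] <- "all"
    tr <- norm_traces |>
      dplyr::group_by(condition = factor(.data[[cc]]), .data$time_min) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean = mean(.data$norm_ratio),
        sd = stats::sd(.data$norm_ratio),
        sem = stats::sd(.data$norm_ratio) / sqrt(dplyr::n()),
        .groups = "drop"
      )
    tr$error_type <- trace_error
    written <- c(written, .write_report_csv(tr, out_dir, "normalized_trace_means.csv"))
    err <- if (trace_error == "sem") tr$sem else tr$sd
    p <- ggplot2::ggplot(tr, ggplot2::aes(
      x = .data$time_min, y = .data$mean,
      colour = .data$condition, fill = .data$condition
    )) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - err, ymax = .data$mean + err),
        alpha = 0.2, colour = NA
      ) +
      ggplot2::geom_line() +
      ggplot2::labs(
        x = "Time (min)", y = "Normalized YFP/CFP",
        title = sprintf("Mean +/- %s normalized ratio", toupper(trace_error))
      )
    ggplot2::ggsave(file.path(out_dir, "normalized_trace_means.pdf"), p,
      width = 6, height = 4
    )
    written <- c(written, file.path(out_dir, "normalized_trace_means.pdf"))
  }

  if (!is.null(responses)) {
    cc <- cond_col(responses) %||% "condition"
    if (!cc %in% names(responses)) responses[[cc]] <- "all"
    keep <- if ("included" %in% names(responses)) responses$included %in% TRUE else TRUE
    resp <- responses[keep, ]
    resp$condition <- factor(resp[[cc]])
    tab <- resp |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean_percent_erk = mean(.data$percent_erk),
        sd = stats::sd(.data$percent_erk),
        sem = stats::sd(.data$percent_erk) / sqrt(dplyr::n()),
        .groups = "drop"
      )
    tab$error_type <- "sem"
    written <- c(written, .write_report_csv(tab, out_dir, "percent_erk_by_condition.csv"))
    written <- c(written, .write_report_csv(
      resp[, c("cell_id", cc, "percent_erk")], out_dir, "percent_erk_cells.csv"
    ))
    p <- ggplot2::ggplot(resp, ggplot2::aes(x = .data$condition, y = .data$percent_erk)) +
      ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
      ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4) +
      ggplot2::labs(x = "Condition", y = "% ERK activity")
    ggplot2::ggsave(file.path(out_dir, "percent_erk_by_condition.pdf"), p,
      width = 5, height = 4
    )
    written <- c(written, file.path(out_dir, "percent_erk_by_condition.pdf"))
  }

  if (!is.null(correlation) && !isTRUE(correlation$flagged)) {
    d <- correlation$data
    pred <- seq(min(d$predictor), max(d$predictor), length.out = 100)
    band <- stats::predict(correlation$fit,
      newdata = data.frame(x = pred),
      interval = "confidence", level = 0.95
    )
    panel <- tibble::tibble(
      predictor = pred, fit = band[, "fit"],
      lwr = band[, "lwr"], upr = band[, "upr"]
    )
    written <- c(written, .write_report_csv(d, out_dir, "correlation_points.csv"))
    written <- c(written, .write_report_csv(panel, out_dir, "correlation_band.csv"))
    xlab <- if (correlation$predictor == "log10_k") {
      "log10 [K+]out (mM)"
    } else {
      "Membrane potential (mV)"
    }
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$predictor, y = .data$percent_erk)) +
      ggplot2::geom_ribbon(
        data = panel,
        ggplot2::aes(x = .data$predictor, ymin = .data$lwr, ymax = .data$upr),
        inherit.aes = FALSE, fill = "grey70", alpha = 0.5
      ) +
      ggplot2::geom_line(
        data = panel, ggplot2::aes(x = .data$predictor, y = .data$fit),
        inherit.aes = FALSE
      ) +
      ggplot2::geom_point(alpha = 0.5) +
      ggplot2::labs(
        x = xlab, y = "% ERK activity",
        title = sprintf("R = %.2f (Pearson)", correlation$r)
      )
    ggplot2::ggsave(file.path(out_dir, "correlation.pdf"), p, width = 5, height = 4)
    written <- c(written, file.path(out_dir, "correlation.pdf"))
  }

  if (!is.null(mitosis)) {
    written <- c(written, .write_report_csv(
      mitosis$ratios, out_dir, "mitosis_ratios.csv"
    ))
    written <- c(written, .write_report_csv(
      mitosis$contrasts, out_dir, "mitosis_contrasts.csv"
    ))
    p <- ggplot2::ggplot(
      mitosis$ratios,
      ggplot2::aes(x = .data$condition, y = .data$ratio)
    ) +
      ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
      ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4) +
      ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
      ggplot2::labs(x = "Condition", y = "Accumulated mitoses / control")
    ggplot2::ggsave(file.path(out_dir, "mitosis_ratios.pdf"), p, width = 5, height = 4)
    written <- c(written, file.path(out_dir, "mitosis_ratios.pdf"))
  }

  if (!is.null(lifetimes)) {
    lt <- lifetimes |>
      dplyr::group_by(.data$time_min) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean = mean(.data$normalized_tau),
        sem = stats::sd(.data$normalized_tau) / sqrt(dplyr::n()),
        .groups = "drop"
      )
    lt$error_type <- "sem"
    written <- c(written, .write_report_csv(lt, out_dir, "normalized_lifetime.csv"))
    p <- ggplot2::ggplot(lt, ggplot2::aes(x = .data$time_min, y = .data$mean)) +
      ggplot2::geom_ribbon(
        ggplot2::aes(
          ymin = .data$mean - .data$sem,
          ymax = .data$mean + .data$sem
        ),
        alpha = 0.2
      ) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Time (min)", y = "Normalized lifetime")
    ggplot2::ggsave(file.path(out_dir, "normalized_lifetime.pdf"), p,
      width = 6, height = 4
    )
    written <- c(written, file.path(out_dir, "normalized_lifetime.pdf"))
  }

  invisible(written)
}
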