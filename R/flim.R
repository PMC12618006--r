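#' Estimate the donor lifetime from a photon-decay histogram
#'
#' Fits a mono-exponential decay to the binned arrival-time histogram by
#' maximum likelihood on the truncated fit window: bin probabilities are
#' `p_j = (exp(-a_j/tau) - exp(-b_j/tau)) / (exp(-A/tau) - exp(-B/tau))`
#' for a window `[A, B)`, and the multinomial log-likelihood is maximised
#' over `tau`. For vanishing bin width this is equivalent to solving the
#' truncated-exponential mean-arrival equation
#' `mean = tau - T / (exp(T/tau) - 1)`. The fit window starts past the
#' instrument-response peak by default (tail fit; no IRF deconvolution).
#'
#' @param hist Decay histogram: tibble/data frame with `bin_start_ns` and
#'   `count` (uniform bin width), e.g. from [simulate_flim_decay()] or
#'   [read_decay_csv()].
#' @param fit_start_ns Start of the fit window (ns), default 0.5.
#' @param fit_end_ns End of the fit window; defaults to the histogram end.
#' @param min_counts Minimum photons required inside the window.
#' @return Estimated lifetime in ns, with attribute `n_photons`.
#' @export
estimate_lifetime <- function(hist, fit_start_ns = 0.5, fit_end_ns = NULL,
                              min_counts = 1000) {
  stopifnot(all(c("bin_start_ns", "count") %in% names(hist)))
  a <- hist$bin_start_ns
  counts <- as.numeric(hist$count)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  widths <- diff(a)
  if (length(widths) == 0L) stop("histogram needs at least two bins", call. = FALSE)
  w <- widths[1]
  if (any(abs(widths - w) > 1e-9 * w)) {
    stop("bins must have uniform width", call. = FALSE)
  }
  if (is.null(fit_end_ns)) fit_end_ns <- max(a) + w
  keep <- a >= fit_start_ns - 1e-12 & (a + w) <= fit_end_ns + 1e-12
  a <- a[keep]
  counts <- counts[keep]
  n <- sum(counts)
  if (length(a) < 2L) stop("fit window contains fewer than two bins", call. = FALSE)
  if (n < min_counts) {
    stop(sprintf(
      "insufficient photons in fit window: %g < %g", n, min_counts
    ), call. = FALSE)
  }
  A <- a[1]
  B <- a[length(a)] + w
  nll <- function(tau) {
    z <- exp(-(a - A) / tau) - exp(-(a + w - A) / tau)
    denom <- 1 - exp(-(B - A) / tau)
    -sum(counts * log(z / denom))
  }
  lower <- w / 20
  upper <- 50 * (B - A)
  opt <- stats::optimize(nll, c(lower, upper), tol = 1e-10)
  tau <- opt$minimum
  if (tau < lower * 1.5 || tau > upper / 1.5) {
    stop(sprintf(
      "lifetime fit did not converge inside (%g, %g) ns; tau at boundary (%g)",
      lower, upper, tau
    ), call. = FALSE)
  }
  structure(tau, n_photons = n)
}

#' Normalize a lifetime time course to its initial reference
#'
#' Divides each lifetime by the mean lifetime over the reference window
#' (default the first 10 min of the recording), per cell when a `cell_id`
#' column is present.
#'
#' @param series Tibble with `time_min` and `tau_ns` (optionally
#'   `cell_id`).
#' @param reference_window Half-open window `c(start, end)` in minutes.
#' @return The input with `normalized_tau` and `reference` columns.
#' @export
normalize_lifetime <- function(series, reference_window = c(0, 10)) {
  stopifnot(
    all(c("time_min", "tau_ns") %in% names(series)),
    length(reference_window) == 2, reference_window[1] < reference_window[2]
  )
  if (any(series$tau_ns <= 0)) stop("lifetimes must be positive", call. = FALSE)
  w1 <- reference_window[1]
  w2 <- reference_window[2]
  if (!"cell_id" %in% names(series)) series$cell_id <- "cell"
  out <- series |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::mutate(
      .n_in = sum(.data$time_min >= w1 & .data$time_min < w2),
      reference = mean(.data$tau_ns[.data$time_min >= w1 & .data$time_min < w2]),
      normalized_tau = .data$tau_ns / .data$reference
    ) |>
    dplyr::ungroup()
  if (any(out$.n_in < 1L)) {
    stop(sprintf(
      "reference window [%g, %g) contains no timepoints for cell(s): %s",
      w1, w2, paste(unique(out$cell_id[out$.n_in < 1L]), collapse = ", ")
    ), call. = FALSE)
  }
  dplyr::select(out, -".n_in")
}

#' Compare donor lifetimes with and without the acceptor
#'
#' FRET shortens the donor lifetime, so co-expression of the acceptor
#' should shift the lifetime distribution down. Reports the mean
#' difference, per-group dispersion, and a Welch two-sample comparison;
#' groups with fewer than 2 cells are flagged (dispersion undefined, no
#' test).
#'
#' @param donor_only Lifetimes (ns) of cells expressing the donor alone.
#' @param donor_plus_acceptor Lifetimes (ns) of cells co-expressing the
#'   acceptor.
#' @return A list: group means and SDs, `difference`
#'   (`donor_plus_acceptor - donor_only`), `fret_direction` (TRUE when the
#'   shift is negative, i.e. FRET-consistent), `statistic`, `df`,
#'   `p_value`, `flagged`.
#' @export
detect_fret_shift <- function(donor_only, donor_plus_acceptor) {
  if (!length(donor_only) || !length(donor_plus_acceptor)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  m1 <- mean(donor_only)
  m2 <- mean(donor_plus_acceptor)
  out <- list(
    n_donor_only = length(donor_only),
    n_with_acceptor = length(donor_plus_acceptor),
    mean_donor_only = m1,
    mean_with_acceptor = m2,
    sd_donor_only = if (length(donor_only) > 1) stats::sd(donor_only) else NA_real_,
    sd_with_acceptor = if (length(donor_plus_acceptor) > 1) {
      stats::sd(donor_plus_acceptor)
    } else {
      NA_real_
    },
    difference = m2 - m1,
    fret_direction = m2 < m1,
    statistic = NA_real_, df = NA_real_, p_value = NA_real_,
    flagged = FALSE
  )
  if (length(donor_only) < 2L || length(donor_plus_acceptor) < 2L) {
    out$flagged <- TRUE
    return(out)
  }
  if (stats::sd(donor_only) == 0 && stats::sd(donor_plus_acceptor) == 0) {
    out$flagged <- m1 != m2
    out$p_value <- if (m1 == m2) 1 else NA_real_
    return(out)
  }
  tt <- stats::t.test(donor_plus_acceptor, donor_only, var.equal = FALSE)
  out$statistic <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p_value <- tt$p.value
  out
}

#' Simulate a perfusion FLIM lifetime time course
#'
#' Models the fast intermolecular-FRET readout (phosphatidylserine
#' clustering): the true donor lifetime relaxes from `tau_rest_ns` toward
#' `tau_rest_ns - depth_ns` with the fast time constant `fast_tau_min`
#' once the stimulus phase starts, and each timepoint's lifetime is then
#' estimated from a simulated photon histogram.
#'
#' @param protocol A [perfusion_protocol()].
#' @param params A [kinetic_params()] (supplies `fast_tau_min`).
#' @param tau_rest_ns Resting donor lifetime (ns).
#' @param depth_ns Depolarization-induced lifetime decrease (ns).
#' @param n_photons Photons per timepoint histogram.
#' @param seed Seed.
#' @return Tibble with `time_min`, `tau_true_ns`, `tau_ns` (estimated).
#' @export
simulate_lifetime_timecourse <- function(protocol, params = kinetic_params(),
                                         tau_rest_ns = 2.375, depth_ns = 0.03,
                                         n_photons = 2e5, seed = 1L) {
  stopifnot(inherits(protocol, "perfusion_protocol"), tau_rest_ns > depth_ns)
  set.seed(as.integer(seed))
  times <- protocol_times(protocol)
  roles <- phase_role_at(protocol, times)
  target <- ifelse(roles %in% c("stimulus", "egf"), 1, 0)
  drive <- .relax_first_order(matrix(target, ncol = 1), times,
    params$fast_tau_min, params$fast_tau_min,
    a0 = 0
  )[, 1]
  tau_true <- tau_rest_ns - depth_ns * drive
  tau_hat <- vapply(tau_true, function(tt) {
    h <- simulate_flim_decay(
      data.frame(tau_ns = tt, fraction = 1), n_photons
    )
    as.numeric(estimate_lifetime(h))
  }, numeric(1))
  tibble::tibble(time_min = times, tau_true_ns = tau_true, tau_ns = tau_hat)
}
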