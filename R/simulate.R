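#' Kinetic parameters of the simulated ERK / biosensor response
#'
#' The simulator's voltage-to-activity transfer is a logistic in membrane
#' potential, `a_ss(V) = 1 / (1 + exp(-(V - v_half) / slope_k))`, and the
#' activity `a(t)` relaxes first-order toward its target with an asymmetric
#' pair of time constants: `tau_on_min` when rising (slow ERK activation
#' over minutes) and `tau_off_min` when falling (fast decay on
#' repolarization, about a minute). After EGF the target becomes
#' `egf_saturation` regardless of voltage. `fast_tau_min` is the time
#' constant of the fast upstream (Ras / phosphatidylserine) channel used by
#' the lifetime simulator.
#'
#' @param v_half Half-activation voltage, mV. Default -25 mV makes -40 mV
#'   sub-threshold and 0 mV near-saturating.
#' @param slope_k Logistic slope factor, mV (> 0).
#' @param tau_on_min,tau_off_min Rise / fall time constants, minutes.
#' @param egf_saturation Activity target under EGF, in (0, 1].
#' @param fast_tau_min Fast-channel time constant, minutes.
#' @return A `kinetic_params` list.
#' @export
kinetic_params <- function(v_half = -25, slope_k = 8, tau_on_min = 5,
                           tau_off_min = 1, egf_saturation = 0.95,
                           fast_tau_min = 1) {
  stopifnot(
    slope_k > 0, tau_on_min > 0, tau_off_min > 0, fast_tau_min > 0,
    egf_saturation > 0, egf_saturation <= 1
  )
  structure(
    list(
      v_half = v_half, slope_k = slope_k, tau_on_min = tau_on_min,
      tau_off_min = tau_off_min, egf_saturation = egf_saturation,
      fast_tau_min = fast_tau_min
    ),
    class = "kinetic_params"
  )
}

#' Population design of a simulated imaging experiment
#'
#' Describes the variability structure the generator emulates: per-dish
#' multiplicative channel gains (probe expression and optical path differ
#' between dishes), per-cell expression and response variability including a
#' non-responder fraction, heterogeneous resting potentials, multiplicative
#' per-frame measurement noise, and a shared photobleaching decay (shared
#' between channels, so the ratio is bleach-invariant by construction).
#'
#' @param n_dishes,cells_per_dish Counts (>= 1).
#' @param dish_gain_sd Log-scale SD of per-dish, per-channel gains.
#' @param cell_response_sd Per-cell response dispersion. In design-targeted
#'   mode ([simulate_population()] with `target_percent`) the per-cell true
#'   %ERK is drawn with SD `100 * cell_response_sd` percentage points; in
#'   voltage-driven mode it is the log-scale SD of the per-cell response
#'   scale.
#' @param nonresponder_fraction Probability that a cell responds neither to
#'   the stimulus nor to EGF (dead/unhealthy cells; the analysis excludes
#'   them).
#' @param resting_potential_range Uniform range of resting potentials, mV.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   per-frame, per-channel noise.
#' @param bleach_rate_per_min Shared exponential photobleaching rate.
#' @param channel_contrast Sensor contrast `delta`: at activity `a` the CFP
#'   channel scales with `1 - delta * a` and YFP with `1 + delta * a`
#'   (anti-correlated channels; default 0.4 gives a ~2x ratio dynamic
#'   range).
#' @param base_intensity Mean background-corrected channel intensity of an
#'   inactive cell (arbitrary camera units).
#' @param expression_sd Log-scale SD of the per-cell expression level.
#' @param seed Integer seed; identical seeds give bitwise-identical output.
#' @return A `population_design` list.
#' @export
population_design <- function(n_dishes = 3, cells_per_dish = 20,
                              dish_gain_sd = 0.2, cell_response_sd = 0.1,
                              nonresponder_fraction = 0.1,
                              resting_potential_range = c(-36, -15),
                              noise_cv = 0.01, bleach_rate_per_min = 0.002,
                              channel_contrast = 0.4, base_intensity = 1000,
                              expression_sd = 0.2, seed = 1L) {
  stopifnot(
    n_dishes >= 1, cells_per_dish >= 1,
    nonresponder_fraction >= 0, nonresponder_fraction <= 1,
    noise_cv >= 0, bleach_rate_per_min >= 0,
    channel_contrast > 0, channel_contrast < 1,
    length(resting_potential_range) == 2,
    resting_potential_range[1] <= resting_potential_range[2]
  )
  structure(
    list(
      n_dishes = as.integer(n_dishes), cells_per_dish = as.integer(cells_per_dish),
      dish_gain_sd = dish_gain_sd, cell_response_sd = cell_response_sd,
      nonresponder_fraction = nonresponder_fraction,
      resting_potential_range = resting_potential_range,
      noise_cv = noise_cv, bleach_rate_per_min = bleach_rate_per_min,
      channel_contrast = channel_contrast, base_intensity = base_intensity,
      expression_sd = expression_sd, seed = as.integer(seed)
    ),
    class = "population_design"
  )
}

# First-order relaxation toward a (piecewise-constant) target, exact per
# step: a(t+dt) = target + (a - target) * exp(-dt/tau), tau chosen by
# direction. `targets` is a T x n matrix; the target in force over
# (t[i-1], t[i]] is the row at the left endpoint, so a frame acquired at a
# switch time still reflects the outgoing phase's dynamics up to that
# instant.
.relax_first_order <- function(targets, times, tau_on, tau_off, a0 = NULL) {
  targets <- as.matrix(targets)
  nt <- nrow(targets)
  if (is.null(a0)) a0 <- targets[1, ]
  out <- matrix(NA_real_, nt, ncol(targets))
  a <- pmin(1, pmax(0, a0))
  out[1, ] <- a
  if (nt > 1) {
    for (i in 2:nt) {
      dt <- times[i] - times[i - 1]
      tg <- targets[i - 1, ]
      tau <- ifelse(tg >= a, tau_on, tau_off)
      a <- tg + (a - tg) * exp(-dt / tau)
      a <- pmin(1, pmax(0, a))
      out[i, ] <- a
    }
  }
  out
}

.a_ss <- function(params, v) {
  stats::plogis((v - params$v_half) / params$slope_k)
}

#' Simulate the ERK activity time course of one cell
#'
#' Integrates the first-order kinetic model: the activity relaxes toward the
#' logistic steady state `a_ss(V)` of the instantaneous voltage with
#' `tau_on_min` when rising and `tau_off_min` when falling; from
#' `egf_onset` onward the target switches to `egf_saturation` regardless of
#' voltage. Activity is confined to [0, 1].
#'
#' @param params A [kinetic_params()].
#' @param voltage Either a tibble with `time_min` and `voltage_mV` (as from
#'   [predicted_voltage_series()]) or a numeric voltage vector matching
#'   `times`.
#' @param times Time grid (min); required when `voltage` is a bare vector.
#' @param egf_onset Optional EGF onset time (min).
#' @param a0 Initial activity; defaults to the steady state of the first
#'   voltage sample.
#' @return Tibble with `time_min`, `voltage_mV`, `activity`.
#' @export
simulate_activity <- function(params, voltage, times = NULL, egf_onset = NULL,
                              a0 = NULL) {
  stopifnot(inherits(params, "kinetic_params"))
  if (is.data.frame(voltage)) {
    times <- voltage$time_min
    v <- voltage$voltage_mV
  } else {
    v <- voltage
  }
  if (is.null(times) || length(times) != length(v)) {
    stop("`times` must accompany `voltage` and match its length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
  target <- .a_ss(params, v)
  if (!is.null(egf_onset)) target[times >= egf_onset] <- params$egf_saturation
  a <- .relax_first_order(matrix(target, ncol = 1), times, params$tau_on_min,
    params$tau_off_min,
    a0 = a0
  )[, 1]
  tibble::tibble(time_min = times, voltage_mV = v, activity = a)
}

# Noise-free measurement map: activity matrix (T x n) -> per-cell true %ERK
# through the same definition the analysis applies (ratio transform,
# reference normalization over `baseline_window`, phase-wise maxima).
.truth_percent <- function(A, times, roles, delta, baseline_window) {
  r <- (1 + delta * A) / (1 - delta * A)
  in_win <- times >= baseline_window[1] & times < baseline_window[2]
  ref <- colMeans(r[in_win, , drop = FALSE])
  norm <- sweep(r, 2, ref, "/")
  base <- colMeans(norm[in_win, , drop = FALSE])
  stim_max <- apply(norm[roles == "stimulus", , drop = FALSE], 2, max)
  egf_max <- apply(norm[roles == "egf", , drop = FALSE], 2, max)
  100 * (stim_max - base) / (egf_max - base)
}

.default_baseline_window <- function(protocol, width = 2) {
  ph <- protocol$phases
  b <- ph[ph$role == "baseline", ][1, ]
  c(max(b$start_min, b$end_min - width), b$end_min)
}

# Map a requested per-cell true %ERK to the stimulus-phase activity target
# by inverting the noise-free measurement map on a grid of steady-state
# targets. Returns list(fun = interpolator, p_max = attainable ceiling).
.percent_inverter <- function(params, times, roles, delta, baseline_window,
                              n_grid = 401) {
  s_grid <- seq(0, 1, length.out = n_grid)
  targets <- matrix(0, length(times), n_grid)
  targets[roles == "stimulus", ] <- matrix(s_grid,
    nrow = sum(roles == "stimulus"),
    ncol = n_grid, byrow = TRUE
  )
  targets[roles == "egf", ] <- params$egf_saturation
  A <- .relax_first_order(targets, times, params$tau_on_min, params$tau_off_min,
    a0 = rep(0, n_grid)
  )
  pct <- .truth_percent(A, times, roles, delta, baseline_window)
  if (any(diff(pct) <= 0)) { # enforce monotone grid for interpolation
    pct <- cummax(pct)
  }
  keep <- !duplicated(pct)
  list(
    fun = stats::approxfun(pct[keep], s_grid[keep], rule = 2, ties = "ordered"),
    p_max = max(pct)
  )
}

# Beta draw on [0, p_max] with exact mean `target` and SD ~ `sd` points.
# Naturally skewed near the edges: near-saturating conditions pile up close
# to the ceiling and weak conditions develop a no-response tail.
.draw_percent <- function(n, target, sd, p_max) {
  if (target <= 0) {
    return(rep(0, n))
  }
  m <- min(target / p_max, 0.995)
  sd_frac <- min(sd / p_max, 0.9 * sqrt(m * (1 - m)))
  nu <- max(m * (1 - m) / sd_frac^2 - 1, 0.5)
  p_max * stats::rbeta(n, m * nu, (1 - m) * nu)
}

#' Simulate a population of two-channel biosensor traces
#'
#' Generates per-cell CFP/YFP intensity traces over a protocol, together
#' with a ground-truth table of per-cell true %ERK activity. Two modes:
#'
#' * **Design-targeted** (`target_percent` given): per-cell true %ERK values
#'   are drawn around `target_percent` (SD `100 * cell_response_sd` points)
#'   and the stimulus-phase activity target of each cell is chosen by
#'   inverting the noise-free measurement map, so the truth table mean
#'   equals the design mean. Used for parameter-recovery studies.
#' * **Voltage-driven** (`target_percent = NULL`): each cell draws a resting
#'   potential; perfusion phases shift the potential by the Nernst
#'   difference of their K+ relative to the baseline solution and clamp
#'   phases use the commanded voltage; activity follows the logistic
#'   transfer scaled by a per-cell lognormal response factor.
#'
#' Channels are anti-correlated in activity (CFP scales with
#' `1 - delta * a`, YFP with `1 + delta * a`), multiplied by dish gains, a
#' per-cell expression level, a shared photobleaching exponential, and
#' per-frame lognormal noise. Non-responders hold their baseline activity
#' throughout, including under EGF.
#'
#' @param design A [population_design()].
#' @param params A [kinetic_params()].
#' @param protocol A [perfusion_protocol()].
#' @param target_percent Optional designed mean %ERK for this protocol's
#'   stimulus condition (0-100).
#' @param baseline_window Reference window (min, half-open); default the
#'   final 2 min of the baseline phase.
#' @param seed Seed override; defaults to `design$seed`.
#' @return A `trace_set`: list with `traces` (tibble `cell_id`, `dish_id`,
#'   `time_min`, `cfp`, `yfp`), `truth` (tibble `cell_id`, `dish_id`,
#'   `responder`, `percent_true`), `protocol`, `params`, `design`.
#' @export
simulate_population <- function(design, params, protocol, target_percent = NULL,
                                baseline_window = NULL, seed = NULL) {
  stopifnot(
    inherits(design, "population_design"), inherits(params, "kinetic_params"),
    inherits(protocol, "perfusion_protocol")
  )
  set.seed(if (is.null(seed)) design$seed else as.integer(seed))
  times <- protocol_times(protocol)
  roles <- phase_role_at(protocol, times)
  if (is.null(baseline_window)) baseline_window <- .default_baseline_window(protocol)
  n <- design$n_dishes * design$cells_per_dish
  dish <- rep(seq_len(design$n_dishes), each = design$cells_per_dish)
  delta <- design$channel_contrast

  gain_cfp <- stats::rlnorm(design$n_dishes, -design$dish_gain_sd^2 / 2, design$dish_gain_sd)
  gain_yfp <- stats::rlnorm(design$n_dishes, -design$dish_gain_sd^2 / 2, design$dish_gain_sd)
  expression <- stats::rlnorm(n, -design$expression_sd^2 / 2, design$expression_sd)
  responder <- stats::runif(n) >= design$nonresponder_fraction

  targets <- matrix(0, length(times), n)
  if (!is.null(target_percent)) {
    inv <- .percent_inverter(params, times, roles, delta, baseline_window)
    p_cell <- .draw_percent(n, target_percent, 100 * design$cell_response_sd, inv$p_max)
    s_cell <- inv$fun(p_cell)
    stim <- roles == "stimulus"
    targets[stim, ] <- matrix(s_cell, sum(stim), n, byrow = TRUE)
    targets[roles == "egf", ] <- params$egf_saturation
    targets[, !responder] <- 0
  } else {
    v_rest <- stats::runif(
      n, design$resting_potential_range[1],
      design$resting_potential_range[2]
    )
    scale <- stats::rlnorm(n, -design$cell_response_sd^2 / 2, design$cell_response_sd)
    ph <- protocol$phases
    k_ref <- ph$k_out_mM[ph$role == "baseline"][1]
    idx <- .phase_index_at(protocol, times)
    for (j in seq_len(nrow(ph))) {
      rows <- idx == j
      if (!any(rows)) next
      if (ph$role[j] == "egf") {
        tg <- matrix(pmin(1, scale * params$egf_saturation), sum(rows), n, byrow = TRUE)
      } else {
        v <- if (is.finite(ph$voltage_mV[j])) {
          rep(ph$voltage_mV[j], n)
        } else if (is.finite(ph$k_out_mM[j]) && is.finite(k_ref)) {
          v_rest + nernst_potential(ph$k_out_mM[j]) - nernst_potential(k_ref)
        } else if (is.finite(ph$k_out_mM[j])) {
          nernst_potential(ph$k_out_mM[j])
        } else {
          stop(sprintf("phase %d has neither `k_out_mM` nor `voltage_mV`", j), call. = FALSE)
        }
        tg <- matrix(pmin(1, scale * .a_ss(params, v)), sum(rows), n, byrow = TRUE)
      }
      targets[rows, ] <- tg
    }
    base_tg <- targets[1, ]
    targets[, !responder] <- matrix(base_tg[!responder], length(times),
      sum(!responder),
      byrow = TRUE
    )
  }

  A <- .relax_first_order(targets, times, params$tau_on_min, params$tau_off_min,
    a0 = targets[1, ]
  )
  percent_true <- .truth_percent(A, times, roles, delta, baseline_window)
  percent_true[!responder] <- 0

  sigma <- sqrt(log(1 + design$noise_cv^2))
  bleach <- exp(-design$bleach_rate_per_min * times)
  noise <- function() {
    if (sigma == 0) {
      matrix(1, length(times), n)
    } else {
      matrix(exp(stats::rnorm(length(times) * n, -sigma^2 / 2, sigma)), length(times), n)
    }
  }
  cfp <- sweep((1 - delta * A) * bleach, 2,
    design$base_intensity * expression * gain_cfp[dish], "*"
  ) * noise()
  yfp <- sweep((1 + delta * A) * bleach, 2,
    design$base_intensity * expression * gain_yfp[dish], "*"
  ) * noise()

  cell_id <- sprintf("c%03d", seq_len(n))
  traces <- tibble::tibble(
    cell_id = rep(cell_id, each = length(times)),
    dish_id = sprintf("d%02d", rep(dish, each = length(times))),
    time_min = rep(times, n),
    cfp = as.vector(cfp),
    yfp = as.vector(yfp)
  )
  truth <- tibble::tibble(
    cell_id = cell_id,
    dish_id = sprintf("d%02d", dish),
    responder = responder,
    percent_true = percent_true
  )
  structure(
    list(
      traces = traces, truth = truth, protocol = protocol,
      params = params, design = design, baseline_window = baseline_window
    ),
    class = "trace_set"
  )
}

#' Simulate several perfusion conditions in one experiment family
#'
#' Runs [simulate_population()] once per stimulus K+ level (design-targeted
#' when `target_percent` is supplied) and row-binds the results, prefixing
#' cell ids with the condition and carrying `k_out` on traces and truth.
#'
#' @param k_levels Stimulus K+ concentrations (mM), one per condition.
#' @param design,params See [simulate_population()].
#' @param target_percent Optional vector of designed mean %ERK per
#'   condition (same length as `k_levels`).
#' @param protocol_fn Function of one argument (`k_stim`) returning the
#'   per-condition protocol; default [standard_perfusion_protocol()]. All
#'   conditions must share the same timing.
#' @return A `trace_set` whose `traces`/`truth` carry a `k_out` column and
#'   whose `protocol` is the (shared-timing) protocol of the first
#'   condition.
#' @export
simulate_conditions <- function(k_levels, design, params, target_percent = NULL,
                                protocol_fn = standard_perfusion_protocol) {
  stopifnot(
    length(k_levels) >= 1,
    is.null(target_percent) || length(target_percent) == length(k_levels)
  )
  sets <- vector("list", length(k_levels))
  for (i in seq_along(k_levels)) {
    prot <- protocol_fn(k_levels[i])
    ts <- simulate_population(design, params, prot,
      target_percent = if (is.null(target_percent)) NULL else target_percent[i],
      seed = design$seed + i
    )
    pre <- sprintf("k%g_", k_levels[i])
    ts$traces$cell_id <- paste0(pre, ts$traces$cell_id)
    ts$truth$cell_id <- paste0(pre, ts$truth$cell_id)
    ts$traces$k_out <- k_levels[i]
    ts$truth$k_out <- k_levels[i]
    sets[[i]] <- ts
  }
  structure(
    list(
      traces = dplyr::bind_rows(lapply(sets, `[[`, "traces")),
      truth = dplyr::bind_rows(lapply(sets, `[[`, "truth")),
      protocol = sets[[1]]$protocol,
      params = params, design = design,
      baseline_window = sets[[1]]$baseline_window
    ),
    class = "trace_set"
  )
}

#' Expected photon counts of a truncated mono-exponential decay
#'
#' Exact expected histogram of `n_photons` arrival times from an
#' exponential decay with lifetime `tau_ns`, truncated to `[0, window_ns)`
#' and binned at `bin_width_ns`. Serves as a noise-free input for estimator
#' consistency checks.
#'
#' @param tau_ns Lifetime (ns).
#' @param n_photons Total photon count.
#' @param bin_width_ns,window_ns Histogram geometry (ns).
#' @return Tibble with `bin_start_ns`, `count` (non-integer in general).
#' @export
expected_decay_counts <- function(tau_ns, n_photons, bin_width_ns = 0.05,
                                  window_ns = 25) {
  stopifnot(tau_ns > 0, n_photons >= 0, bin_width_ns > 0, window_ns > bin_width_ns)
  a <- seq(0, window_ns - bin_width_ns / 2, by = bin_width_ns)
  b <- a + bin_width_ns
  p <- (exp(-a / tau_ns) - exp(-b / tau_ns)) / (1 - exp(-window_ns / tau_ns))
  tibble::tibble(bin_start_ns = a, count = n_photons * p)
}

#' Simulate a TCSPC photon-decay histogram
#'
#' Photon arrival times are drawn from a mixture of exponential decays
#' truncated to the acquisition window `[0, window_ns)` and binned. A
#' mixture with a short-lifetime component models the FRET-quenched donor
#' population.
#'
#' @param components Data frame (or coercible) with columns `tau_ns` (> 0)
#'   and `fraction` (summing to 1).
#' @param n_photons Number of photons to draw.
#' @param bin_width_ns,window_ns Histogram geometry (ns).
#' @param seed Optional seed for reproducibility.
#' @return Tibble with `bin_start_ns`, `count` (integer counts summing to
#'   `n_photons`); attributes `bin_width_ns`, `window_ns`.
#' @export
simulate_flim_decay <- function(components, n_photons, bin_width_ns = 0.05,
                                window_ns = 25, seed = NULL) {
  components <- as.data.frame(components)
  if (nrow(components) == 0L) stop("`components` must be non-empty", call. = FALSE)
  stopifnot(all(c("tau_ns", "fraction") %in% names(components)))
  if (any(components$tau_ns <= 0)) stop("component lifetimes must be positive", call. = FALSE)
  if (abs(sum(components$fraction) - 1) > 1e-8) {
    stop("component fractions must sum to 1", call. = FALSE)
  }
  if (n_photons < 0) stop("`n_photons` must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  edges <- seq(0, window_ns, by = bin_width_ns)
  counts <- integer(length(edges) - 1L)
  if (n_photons > 0) {
    comp <- sample.int(nrow(components), n_photons,
      replace = TRUE,
      prob = components$fraction
    )
    tau <- components$tau_ns[comp]
    u <- stats::runif(n_photons)
    t <- -tau * log(1 - u * (1 - exp(-window_ns / tau))) # inverse CDF, truncated
    counts <- tabulate(findInterval(t, edges, rightmost.closed = TRUE),
      nbins = length(edges) - 1L
    )
  }
  out <- tibble::tibble(bin_start_ns = edges[-length(edges)], count = counts)
  attr(out, "bin_width_ns") <- bin_width_ns
  attr(out, "window_ns") <- window_ns
  out
}

#' A set of cytokinesis events from one recording
#'
#' @param experiment_id Identifier shared by arms of the same experiment.
#' @param condition Condition label (e.g. `"5K"`, `"15K"`, `"15K+U"`).
#' @param event_times_h Event times in hours, within `[0, span]`.
#' @param observation_span_h Length of the recording, hours.
#' @return A `mitosis_record` list.
#' @export
mitosis_record <- function(experiment_id, condition, event_times_h,
                           observation_span_h) {
  stopifnot(observation_span_h > 0)
  if (length(event_times_h) && (any(event_times_h < 0) ||
    any(event_times_h > observation_span_h))) {
    stop("event times must lie within [0, observation_span_h]", call. = FALSE)
  }
  structure(
    list(
      experiment_id = as.character(experiment_id),
      condition = as.character(condition),
      event_times_h = sort(as.numeric(event_times_h)),
      observation_span_h = observation_span_h
    ),
    class = "mitosis_record"
  )
}

#' Simulate cytokinesis events as a homogeneous Poisson process
#'
#' @param rate_per_hour Event rate (>= 0).
#' @param duration_h Observation span (hours).
#' @param seed Optional seed.
#' @param experiment_id,condition Labels attached to the record.
#' @return A [mitosis_record()].
#' @export
simulate_mitosis_events <- function(rate_per_hour, duration_h, seed = NULL,
                                    experiment_id = "exp1", condition = "5K") {
  if (rate_per_hour < 0) stop("`rate_per_hour` must be non-negative", call. = FALSE)
  stopifnot(duration_h > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- stats::rpois(1, rate_per_hour * duration_h)
  mitosis_record(experiment_id, condition, sort(stats::runif(n, 0, duration_h)), duration_h)
}
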