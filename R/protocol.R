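# Physical constants (CODATA 2018)
.R_GAS <- 8.314462618 # J mol^-1 K^-1
.FARADAY <- 96485.33212 # C mol^-1

.PHASE_ROLES <- c("baseline", "stimulus", "repolarized", "egf")

#' Nernst equilibrium potential for potassium
#'
#' Predicts the membrane potential at which there is no net K+ flux,
#' `E = (RT/F) * ln([K+]out / [K+]in)`, in millivolts. Used to map the
#' extracellular K+ concentration of a perfusion solution to a predicted
#' membrane potential; the prediction ignores all other conductances and is
#' labelled "predicted", never "measured".
#'
#' @param k_out Extracellular K+ concentration (mM). Vectorised.
#' @param k_in Intracellular K+ concentration (mM). Default 145 mM, matching
#'   a typical KCl patch-pipette solution.
#' @param temperature Absolute temperature in Kelvin (default 298.15 K).
#' @return Predicted potential(s) in mV. `59.16 mV` per tenfold change in
#'   `k_out` at 298.15 K.
#' @examples
#' nernst_potential(145) # 0 mV: equal concentrations
#' nernst_potential(14.5, 145) # about -59.2 mV, one decade down
#' @export
nernst_potential <- function(k_out, k_in = 145, temperature = 298.15) {
  if (!all(is.finite(k_out)) || any(k_out <= 0)) {
    stop("`k_out` must be finite and positive (mM)", call. = FALSE)
  }
  if (!all(is.finite(k_in)) || any(k_in <= 0)) {
    stop("`k_in` must be finite and positive (mM)", call. = FALSE)
  }
  if (!all(is.finite(temperature)) || any(temperature <= 0)) {
    stop("`temperature` must be positive (Kelvin)", call. = FALSE)
  }
  1000 * .R_GAS * temperature / .FARADAY * log(k_out / k_in)
}

#' Define a perfusion solution condition
#'
#' @param label Condition label, e.g. `"5K"`, `"145K"`.
#' @param k_out Extracellular K+ concentration (mM), `> 0`.
#' @param calcium_present Whether the solution contains Ca2+ (EGTA-buffered
#'   Ca-free solutions set this to `FALSE`).
#' @param egf Optional EGF content, stored verbatim as
#'   `list(value =, unit =)`; no unit conversion is attempted.
#' @return A `solution_condition` list.
#' @export
solution_condition <- function(label, k_out, calcium_present = TRUE, egf = NULL) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(k_out) || length(k_out) != 1L || !is.finite(k_out) || k_out <= 0) {
    stop("`k_out` must be a single positive concentration (mM)", call. = FALSE)
  }
  structure(
    list(label = label, k_out = k_out, calcium_present = isTRUE(calcium_present), egf = egf),
    class = "solution_condition"
  )
}

.canonical_phase_cols <- function(phases) {
  phases <- tibble::as_tibble(phases)
  for (col in c("k_out_mM", "voltage_mV")) {
    if (!col %in% names(phases)) phases[[col]] <- NA_real_
  }
  if (!"label" %in% names(phases)) phases[["label"]] <- NA_character_
  if (!"egf" %in% names(phases)) phases[["egf"]] <- NA_character_
  phases[, c("start_min", "end_min", "role", "label", "k_out_mM", "voltage_mV", "egf")]
}

#' Construct an experimental timeline of perfusion / clamp phases
#'
#' A protocol is an ordered, contiguous, non-overlapping set of half-open
#' phases `[start_min, end_min)`, each with a role (`baseline`, `stimulus`,
#' `repolarized`, `egf`) and either an extracellular K+ concentration
#' (perfusion) or a clamped voltage. A frame acquired exactly at a switch
#' time belongs to the new phase.
#'
#' @param phases Data frame with columns `start_min`, `end_min`, `role`, and
#'   at least one of `k_out_mM`, `voltage_mV` per phase; optional `label`
#'   and `egf`.
#' @param frame_interval_min Imaging frame interval in minutes.
#' @return A `perfusion_protocol` object.
#' @seealso [standard_perfusion_protocol()], [clamp_protocol()],
#'   [read_protocol()]
#' @export
perfusion_protocol <- function(phases, frame_interval_min = 1) {
  phases <- .canonical_phase_cols(phases)
  n <- nrow(phases)
  if (n == 0L) stop("protocol needs at least one phase", call. = FALSE)
  if (!is.numeric(frame_interval_min) || frame_interval_min <= 0) {
    stop("`frame_interval_min` must be positive", call. = FALSE)
  }
  for (i in seq_len(n)) {
    ph <- phases[i, ]
    if (!is.finite(ph$start_min) || !is.finite(ph$end_min) || ph$start_min >= ph$end_min) {
      stop(sprintf("phase %d: start_min must be < end_min", i), call. = FALSE)
    }
    if (!ph$role %in% .PHASE_ROLES) {
      stop(sprintf(
        "phase %d: unknown role '%s' (expected one of %s)",
        i, ph$role, paste(.PHASE_ROLES, collapse = ", ")
      ), call. = FALSE)
    }
    if (i > 1L && !isTRUE(all.equal(phases$end_min[i - 1L], ph$start_min))) {
      stop(sprintf("phase %d: phases must be contiguous and ordered", i), call. = FALSE)
    }
  }
  if (sum(phases$role == "egf") > 1L) {
    stop("at most one egf phase is allowed", call. = FALSE)
  }
  b <- which(phases$role == "baseline")
  s <- which(phases$role == "stimulus")
  if (length(b) && length(s) && min(s) < min(b)) {
    stop("baseline phase must precede the stimulus phase", call. = FALSE)
  }
  structure(
    list(phases = phases, frame_interval_min = frame_interval_min),
    class = "perfusion_protocol"
  )
}

#' @export
print.perfusion_protocol <- function(x, ...) {
  cat(sprintf(
    "<perfusion_protocol> %d phases, %.4g-%.4g min, frame interval %.4g min\n",
    nrow(x$phases), min(x$phases$start_min), max(x$phases$end_min), x$frame_interval_min
  ))
  print(x$phases)
  invisible(x)
}

#' Recording span of a protocol
#' @param protocol A [perfusion_protocol()].
#' @return `c(start, end)` in minutes.
#' @export
protocol_span <- function(protocol) {
  stopifnot(inherits(protocol, "perfusion_protocol"))
  c(min(protocol$phases$start_min), max(protocol$phases$end_min))
}

#' Frame acquisition times implied by a protocol
#'
#' Frames are placed at `start, start + dt, ...` strictly before the end of
#' the recording (half-open span), so every frame lies inside some phase.
#' @inheritParams protocol_span
#' @return Numeric vector of times (min).
#' @export
protocol_times <- function(protocol) {
  sp <- protocol_span(protocol)
  seq(sp[1], sp[2] - protocol$frame_interval_min / 2, by = protocol$frame_interval_min)
}

.phase_index_at <- function(protocol, t) {
  ph <- protocol$phases
  idx <- vapply(t, function(tt) {
    j <- which(ph$start_min <= tt & tt < ph$end_min)
    if (length(j) != 1L) NA_integer_ else j
  }, integer(1))
  if (anyNA(idx)) {
    bad <- t[is.na(idx)]
    stop(sprintf(
      "time(s) outside recording span [%g, %g): %s",
      min(ph$start_min), max(ph$end_min),
      paste(utils::head(bad, 5), collapse = ", ")
    ), call. = FALSE)
  }
  idx
}

#' Locate the protocol phase containing a time point
#'
#' Phase boundaries follow the half-open convention `[start, end)`: a time
#' equal to a switch time belongs to the incoming phase.
#'
#' @inheritParams protocol_span
#' @param t Time(s) in minutes, inside the recording span.
#' @return One phase row per element of `t` (a tibble).
#' @export
phase_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "perfusion_protocol"))
  protocol$phases[.phase_index_at(protocol, t), ]
}

#' Phase role per time point
#' @inheritParams phase_at
#' @return Character vector of roles, one per element of `t`.
#' @export
phase_role_at <- function(protocol, t) {
  phase_at(protocol, t)$role
}

#' Predicted membrane potential over a protocol
#'
#' Clamped phases return the commanded voltage verbatim; perfusion phases
#' return the Nernst prediction for their K+ concentration. The result is
#' piecewise constant with steps exactly at phase boundaries.
#'
#' @inheritParams phase_at
#' @param k_in Intracellular K+ (mM) for the Nernst prediction.
#' @param temperature Kelvin.
#' @param times Evaluation times; defaults to the protocol frame grid.
#' @return Tibble with `time_min`, `voltage_mV`.
#' @export
predicted_voltage_series <- function(protocol, k_in = 145, temperature = 298.15,
                                     times = NULL) {
  stopifnot(inherits(protocol, "perfusion_protocol"))
  if (is.null(times)) times <- protocol_times(protocol)
  idx <- .phase_index_at(protocol, times)
  ph <- protocol$phases
  v_phase <- numeric(nrow(ph))
  for (i in seq_len(nrow(ph))) {
    if (is.finite(ph$voltage_mV[i])) {
      v_phase[i] <- ph$voltage_mV[i]
    } else if (is.finite(ph$k_out_mM[i])) {
      v_phase[i] <- nernst_potential(ph$k_out_mM[i], k_in, temperature)
    } else {
      stop(sprintf("phase %d has neither `k_out_mM` nor `voltage_mV`", i), call. = FALSE)
    }
  }
  tibble::tibble(time_min = times, voltage_mV = v_phase[idx])
}

#' Standard high-K+ perfusion protocol
#'
#' Baseline in low-K+ solution, switch to the stimulus K+ concentration,
#' then EGF added at the end of the recording (EGF is prepared in low-K+
#' solution). Default timing: baseline 0-10 min, stimulus 10-30 min,
#' EGF 30-45 min.
#'
#' @param k_stim Stimulus-phase K+ concentration (mM).
#' @param k_baseline Baseline (and EGF-phase) K+ concentration (mM).
#' @param t_stim,t_egf,t_end Switch times and recording end (min).
#' @param frame_interval_min Frame interval (min).
#' @param egf EGF content of the final phase, stored verbatim.
#' @return A [perfusion_protocol()].
#' @export
standard_perfusion_protocol <- function(k_stim, k_baseline = 5, t_stim = 10,
                                        t_egf = 30, t_end = 45,
                                        frame_interval_min = 1, egf = "10 nM") {
  phases <- tibble::tibble(
    start_min = c(0, t_stim, t_egf),
    end_min = c(t_stim, t_egf, t_end),
    role = c("baseline", "stimulus", "egf"),
    label = c(
      sprintf("%gK", k_baseline), sprintf("%gK", k_stim),
      sprintf("%gK+EGF", k_baseline)
    ),
    k_out_mM = c(k_baseline, k_stim, k_baseline),
    egf = c(NA_character_, NA_character_, as.character(egf))
  )
  perfusion_protocol(phases, frame_interval_min)
}

#' Voltage-clamp protocol with a depolarizing step
#'
#' Hold, depolarize, repolarize, then perfuse EGF while holding. Default
#' timing mirrors a clamp experiment: hold 0-5 min, step 5-10 min,
#' repolarized 10-15 min, EGF 15-25 min.
#'
#' @param v_step Step (depolarized) potential, mV.
#' @param v_hold Holding potential, mV (default -80).
#' @param t_step,t_repol,t_egf,t_end Switch times and recording end (min).
#' @param frame_interval_min Frame interval (min).
#' @param egf EGF content of the final phase.
#' @return A [perfusion_protocol()] whose phases carry `voltage_mV`.
#' @export
clamp_protocol <- function(v_step, v_hold = -80, t_step = 5, t_repol = 10,
                           t_egf = 15, t_end = 25, frame_interval_min = 1,
                           egf = "10 nM") {
  phases <- tibble::tibble(
    start_min = c(0, t_step, t_repol, t_egf),
    end_min = c(t_step, t_repol, t_egf, t_end),
    role = c("baseline", "stimulus", "repolarized", "egf"),
    label = c(
      sprintf("hold %g mV", v_hold), sprintf("step %g mV", v_step),
      sprintf("repol %g mV", v_hold), "EGF"
    ),
    voltage_mV = c(v_hold, v_step, v_hold, v_hold),
    egf = c(NA_character_, NA_character_, NA_character_, as.character(egf))
  )
  perfusion_protocol(phases, frame_interval_min)
}
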