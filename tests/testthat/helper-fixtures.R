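# Shared fixtures and independent oracles used across the suite.

# Three-phase perfusion timeline matching the standard experiment:
# baseline [0,10), stimulus [10,30), EGF [30,45), 1-min frames.
fixture_protocol <- function(k_stim = 145) {
  standard_perfusion_protocol(k_stim)
}

# Hand-built normalized-trace tibble: one value per (cell, time).
fixture_norm_traces <- function(cell_id, times, norm) {
  tibble::tibble(cell_id = cell_id, time_min = times, norm_ratio = norm)
}

# Truncated-exponential mean arrival time on [0, T]: the closed-form oracle
# the lifetime estimator must agree with in the fine-bin limit.
trunc_exp_mean <- function(tau, window) {
  tau - window / (exp(window / tau) - 1)
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# group-label assignments (distance of the rank sum from its null mean).
wilcox_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  m <- length(x)
  rk <- rank(pooled)
  obs <- sum(rk[seq_len(m)])
  centre <- m * (n + 1) / 2
  sums <- apply(utils::combn(n, m), 2, function(ix) sum(rk[ix]))
  mean(abs(sums - centre) >= abs(obs - centre) - 1e-9)
}

# Textbook Pearson correlation, written out (independent of cor()).
pearson_by_hand <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Small two-channel trace with flat baseline, a stimulus bump and a larger
# EGF bump; integer-valued intensities so offset arithmetic is exact.
fixture_two_channel_traces <- function() {
  prot <- fixture_protocol()
  times <- protocol_times(prot)
  bump <- function(stim_level, egf_level) {
    lvl <- rep(1, length(times))
    lvl[times >= 10 & times < 30] <- stim_level
    lvl[times >= 30] <- egf_level
    lvl
  }
  make_cell <- function(id, cfp0, yfp0, stim, egf) {
    tibble::tibble(
      cell_id = id, dish_id = "d01", time_min = times,
      cfp = cfp0 * (2 - bump(stim, egf)),
      yfp = yfp0 * bump(stim, egf)
    )
  }
  dplyr::bind_rows(
    make_cell("a", 64, 128, 1.25, 1.5),
    make_cell("b", 32, 64, 1.125, 1.75)
  )
}
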