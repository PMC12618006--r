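test_that("activity kinetics follow the first-order logistic model", {
  params <- kinetic_params(v_half = -30, slope_k = 10, tau_on_min = 5, tau_off_min = 1)
  times <- seq(0, 60)

  # a cell started at its steady state stays there (fixed point)
  v_const <- rep(-20, length(times))
  a <- simulate_activity(params, v_const, times)
  expect_equal(a$activity, rep(plogis(1), length(times)), tolerance = 1e-12)

  # step -80 -> 0 mV approaches the closed-form sigmoid asymptote
  v_step <- ifelse(times < 5, -80, 0)
  a <- simulate_activity(params, v_step, times)
  expect_equal(tail(a$activity, 1), 1 / (1 + exp(-3)), tolerance = 1e-4)
  expect_equal(1 / (1 + exp(-3)), 0.9526, tolerance = 1e-4)
  # rising segment is monotone and inside [0, 1]
  expect_true(all(diff(a$activity[times >= 5]) >= 0))
  expect_true(all(a$activity >= 0 & a$activity <= 1))

  # repolarization decays by a factor e^-1 per minute toward a_ss(-80)
  v_updown <- ifelse(times < 30, 0, -80)
  a <- simulate_activity(params, v_updown, times)
  a_lo <- plogis((-80 + 30) / 10)
  dec <- a$activity[times >= 30] - a_lo
  expect_equal(dec[2] / dec[1], exp(-1), tolerance = 1e-9)
  expect_equal(dec[4] / dec[3], exp(-1), tolerance = 1e-9)

  # after EGF onset the target ignores voltage
  a <- simulate_activity(params, rep(-80, length(times)), times, egf_onset = 30)
  expect_lt(a$activity[times == 29], 0.01)
  expect_equal(tail(a$activity, 1), params$egf_saturation, tolerance = 5e-3)
})

test_that("population simulation is seeded-deterministic and honours the design", {
  design <- population_design(n_dishes = 3, cells_per_dish = 20, seed = 7)
  params <- kinetic_params()
  prot <- fixture_protocol()

  ts1 <- simulate_population(design, params, prot, target_percent = 50)
  ts2 <- simulate_population(design, params, prot, target_percent = 50)
  expect_identical(ts1$traces, ts2$traces) # bitwise reproducible
  expect_identical(ts1$truth, ts2$truth)

  expect_identical(nrow(ts1$truth), 60L)
  expect_setequal(ts1$truth$cell_id, unique(ts1$traces$cell_id))

  # all-non-responder population: truth %ERK is all zero, traces flat up to noise
  dead <- population_design(
    n_dishes = 1, cells_per_dish = 10,
    nonresponder_fraction = 1, noise_cv = 0, seed = 3
  )
  ts <- simulate_population(dead, params, prot, target_percent = 80)
  expect_true(all(ts$truth$percent_true == 0))
  flat <- ts$traces |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(spread = diff(range(yfp / cfp)))
  expect_true(all(flat$spread < 1e-9))
})

test_that("noise-free single-cell trace is a monotone transform of activity", {
  design <- population_design(
    n_dishes = 1, cells_per_dish = 1, noise_cv = 0,
    bleach_rate_per_min = 0, nonresponder_fraction = 0,
    dish_gain_sd = 0, expression_sd = 0, seed = 5
  )
  ts <- simulate_population(design, kinetic_params(), fixture_protocol(),
    target_percent = 60
  )
  ratio <- ts$traces$yfp / ts$traces$cfp
  # ratio rises through the stimulus phase, jumps further under EGF:
  # a strictly monotone function of the underlying activity
  delta <- ts$design$channel_contrast
  a_implied <- (ratio / ratio[1] - 1) / (delta * (ratio / ratio[1] + 1))
  expect_true(all(a_implied >= -1e-12 & a_implied <= 1))
  expect_true(all(diff(ratio[ts$traces$time_min >= 10 & ts$traces$time_min < 30]) > 0))
})

test_that("designed mean %ERK is realised by the truth table", {
  design <- population_design(
    n_dishes = 2, cells_per_dish = 40,
    nonresponder_fraction = 0, seed = 21
  )
  for (target in c(10, 50, 90)) {
    ts <- simulate_population(design, kinetic_params(), fixture_protocol(),
      target_percent = target
    )
    se <- 10 / sqrt(80) # cell SD is 100 * cell_response_sd = 10 points
    expect_equal(mean(ts$truth$percent_true), target, tolerance = 4 * se / target)
  }
})

test_that("photon-decay simulation matches truncated-exponential moments", {
  # zero photons give an all-zero histogram of the right geometry
  h0 <- simulate_flim_decay(data.frame(tau_ns = 2.5, fraction = 1), 0)
  expect_true(all(h0$count == 0))
  expect_identical(nrow(h0), as.integer(25 / 0.05))

  # seeded determinism
  comp <- data.frame(tau_ns = c(2.375, 1.0), fraction = c(0.7, 0.3))
  h1 <- simulate_flim_decay(comp, 1e4, seed = 9)
  h2 <- simulate_flim_decay(comp, 1e4, seed = 9)
  expect_identical(h1$count, h2$count)
  expect_identical(sum(h1$count), 10000L)

  # single component: empirical mean arrival matches the closed-form
  # truncated-exponential mean within Monte-Carlo error
  h <- simulate_flim_decay(data.frame(tau_ns = 2.5, fraction = 1), 1e6,
    seed = 2, window_ns = 25
  )
  centres <- h$bin_start_ns + 0.025
  emp_mean <- sum(centres * h$count) / sum(h$count)
  expect_equal(emp_mean, trunc_exp_mean(2.5, 25), tolerance = 4 * 2.5 / sqrt(1e6) / 2.5)

  expect_error(simulate_flim_decay(data.frame(), 10), "non-empty")
  expect_error(
    simulate_flim_decay(data.frame(tau_ns = 2, fraction = 0.5), 10),
    "sum to 1"
  )
  expect_error(
    simulate_flim_decay(data.frame(tau_ns = -1, fraction = 1), 10),
    "positive"
  )
})

test_that("mitosis event simulation has Poisson moments and seeded determinism", {
  expect_identical(
    length(simulate_mitosis_events(0, 6, seed = 1)$event_times_h), 0L
  )
  r1 <- simulate_mitosis_events(10, 6, seed = 42)
  r2 <- simulate_mitosis_events(10, 6, seed = 42)
  expect_identical(r1$event_times_h, r2$event_times_h)
  expect_error(simulate_mitosis_events(-1, 6), "non-negative")

  counts <- vapply(
    1:1000,
    function(s) length(simulate_mitosis_events(10, 6, seed = s)$event_times_h),
    numeric(1)
  )
  # Poisson(60): mean 60 (SE 0.24), variance 60 (SE ~2.7)
  expect_equal(mean(counts), 60, tolerance = 4 * sqrt(60 / 1000) / 60)
  expect_equal(var(counts), 60, tolerance = 4 * 60 * sqrt(2 / 999) / 60)
  expect_true(all(counts >= 0))
})

test_that("rendered stacks reproduce traces exactly in the noise-free limit", {
  design <- population_design(
    n_dishes = 1, cells_per_dish = 4, noise_cv = 0,
    bleach_rate_per_min = 0, nonresponder_fraction = 0,
    dish_gain_sd = 0, expression_sd = 0, seed = 8
  )
  prot <- standard_perfusion_protocol(145, t_end = 35) # keep the stack small
  ts <- simulate_population(design, kinetic_params(), prot, target_percent = 70)
  ts$traces$cfp <- round(ts$traces$cfp)
  ts$traces$yfp <- round(ts$traces$yfp)

  rend <- render_image_stack(ts$traces, background_offset = 100, shot_noise = FALSE)
  got <- extract_cell_traces(rend$stack, rend$masks, rend$background_rois,
    cell_ids = rend$cell_ids
  )
  ref <- dplyr::arrange(ts$traces[, c("cell_id", "time_min", "cfp", "yfp")],
    cell_id, time_min)
  got <- dplyr::arrange(got, cell_id, time_min)
  # offset of 100 cancels exactly against the matching background ROIs
  expect_equal(got$cfp, ref$cfp, tolerance = 1e-12)
  expect_equal(got$yfp, ref$yfp, tolerance = 1e-12)

  # seeded shot-noise render is reproducible
  s1 <- render_image_stack(ts$traces, shot_noise = TRUE, seed = 4)
  s2 <- render_image_stack(ts$traces, shot_noise = TRUE, seed = 4)
  expect_identical(s1$stack, s2$stack)

  # impossible placements raise rather than overlap
  big <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:200), time_min = 0, cfp = 5, yfp = 5
  )
  expect_error(render_image_stack(big), "cannot place")
})
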