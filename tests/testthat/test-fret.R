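test_that("background subtraction pools ROI pixels and flags impossible cells", {
  frame <- matrix(105, 20, 20)
  rois <- list(c(row0 = 1, row1 = 2, col0 = 1, col1 = 2))
  frame[1:2, 1:2] <- 100
  corr <- subtract_background(frame, rois)
  expect_equal(attr(corr, "background"), 100)
  expect_equal(corr[10, 10], 5)

  # two equally sized ROIs reading 90 and 110 -> subtract their mean, 100
  frame2 <- matrix(105, 20, 20)
  frame2[1:2, 1:2] <- 90
  frame2[19:20, 19:20] <- 110
  rois2 <- list(
    c(row0 = 1, row1 = 2, col0 = 1, col1 = 2),
    c(row0 = 19, row1 = 20, col0 = 19, col1 = 20)
  )
  expect_equal(attr(subtract_background(frame2, rois2), "background"), 100)
  expect_error(subtract_background(frame, list()), "background ROI")

  # a cell dimmer than the background is dropped with a reason
  stack <- array(10, c(12, 12, 2))
  stack[6:7, 6:7, ] <- 8 # below the background of 10
  masks <- matrix(0L, 12, 12)
  masks[6:7, 6:7] <- 1L
  rois3 <- list(c(row0 = 1, row1 = 2, col0 = 1, col1 = 2))
  out <- extract_cell_traces(stack, masks, rois3)
  expect_identical(nrow(out), 0L)
  dropped <- attr(out, "dropped")
  expect_identical(nrow(dropped), 1L)
  expect_match(dropped$reason, "non-positive")

  # empty mask is an error naming the problem
  expect_error(
    extract_cell_traces(stack, matrix(0L, 12, 12), rois3),
    "no cell ROIs"
  )
})

test_that("ratio and reference normalization follow their defining arithmetic", {
  tr <- tibble::tibble(
    cell_id = "a", time_min = 0:1, cfp = c(1, 2), yfp = c(2, 4)
  )
  expect_equal(compute_ratio(tr)$ratio, c(2, 2))
  # scaling YFP by g scales the ratio by exactly g
  tr_g <- dplyr::mutate(tr, yfp = yfp * 1.7)
  expect_equal(compute_ratio(tr_g)$ratio, 1.7 * c(2, 2))
  expect_error(
    compute_ratio(dplyr::mutate(tr, cfp = c(1, 0))),
    "non-positive CFP.*a@1"
  )

  rt <- tibble::tibble(
    cell_id = "a", time_min = 0:2, ratio = c(2.0, 2.0, 2.2)
  )
  nt <- normalize_traces(rt, c(0, 2))
  expect_equal(nt$norm_ratio, c(1.0, 1.0, 1.1))
  expect_equal(unique(nt$reference), 2.0)

  # the window is half-open: [8, 10) on 1-min sampling uses t = 8 and 9 only
  rt2 <- tibble::tibble(
    cell_id = "a", time_min = 0:10,
    ratio = c(rep(1, 8), 2, 4, 100)
  )
  nt2 <- normalize_traces(rt2, c(8, 10))
  expect_equal(unique(nt2$reference), 3) # mean(2, 4); t = 10 excluded
  # window mean of the normalized output is 1 by construction
  expect_equal(mean(nt2$norm_ratio[nt2$time_min >= 8 & nt2$time_min < 10]), 1,
    tolerance = 1e-12
  )
  expect_error(normalize_traces(rt2, c(8, 9)), "fewer than 2")
})

test_that("percent_erk implements the baseline-subtracted ratio of maxima", {
  prot <- fixture_protocol()
  times <- protocol_times(prot)
  shape <- function(stim_max, egf_max) {
    n <- rep(1, length(times))
    n[times == 20] <- stim_max
    n[times == 35] <- egf_max
    n
  }
  nt <- dplyr::bind_rows(
    fixture_norm_traces("half", times, shape(1.05, 1.10)),
    fixture_norm_traces("full", times, shape(1.20, 1.20)),
    fixture_norm_traces("none", times, shape(1.00, 1.30))
  )
  resp <- percent_erk(nt, prot)
  expect_equal(resp$percent_erk[resp$cell_id == "half"], 50.0)
  expect_equal(resp$percent_erk[resp$cell_id == "full"], 100.0)
  expect_equal(resp$percent_erk[resp$cell_id == "none"], 0.0)
  expect_equal(resp$baseline[resp$cell_id == "half"], 1.0)

  # without baseline subtraction the statistic is the plain ratio of maxima
  resp_raw <- percent_erk(nt, prot, subtract_baseline = FALSE)
  expect_equal(resp_raw$percent_erk[resp_raw$cell_id == "half"],
    100 * 1.05 / 1.10,
    tolerance = 1e-12
  )

  # a cell whose EGF maximum never exceeds baseline has no defined percent
  flat <- fixture_norm_traces("flat", times, rep(1, length(times)))
  expect_true(is.na(percent_erk(flat, prot)$percent_erk))
})

test_that("the EGF-response exclusion rule applies the k-sigma criterion", {
  prot <- fixture_protocol()
  times <- protocol_times(prot)
  set.seed(1)
  base_noise <- function(sd) {
    n <- 1 + rnorm(length(times), 0, sd)
    n / mean(n[times >= 8 & times < 10])
  }
  weak <- base_noise(0.01)
  weak[times == 35] <- max(weak) + 0.001 # egf bump ~ noise
  strong <- base_noise(0.01)
  strong[times == 35] <- 1.20 # clear EGF response
  nt <- dplyr::bind_rows(
    fixture_norm_traces("weak", times, weak),
    fixture_norm_traces("strong", times, strong)
  )
  resp <- exclude_nonresponders(percent_erk(nt, prot), nt, prot, k_sigma = 3)
  expect_false(resp$included[resp$cell_id == "weak"])
  expect_true(resp$included[resp$cell_id == "strong"])
  expect_match(resp$reason[resp$cell_id == "weak"], "baseline SD")

  # simulated population: exclusion recovers the designed non-responder rate
  design <- population_design(
    n_dishes = 2, cells_per_dish = 50, noise_cv = 0.005,
    nonresponder_fraction = 0.3, seed = 17
  )
  ts <- simulate_population(design, kinetic_params(), prot, target_percent = 60)
  q <- quantify_traceset(ts)
  n_excluded <- sum(!q$responses$included)
  # binomial n = 100, p = 0.3: allow 4 SD around the designed count
  expect_lt(abs(n_excluded - 30), 4 * sqrt(100 * 0.3 * 0.7))
  # every true responder is retained (EGF response is far above noise); the
  # 3-sigma rule is compared against a maximum over the EGF frames, so a
  # minority of non-responders leak through, but most are caught
  merged <- dplyr::inner_join(q$responses, ts$truth, by = "cell_id")
  expect_true(all(merged$included[merged$responder]))
  expect_gt(mean(!merged$included[!merged$responder]), 0.5)
})

test_that("phase extrema summarise each phase with its own statistic", {
  prot <- clamp_protocol(-20, t_end = 20, frame_interval_min = 2.5)
  times <- protocol_times(prot) # 2 frames per phase
  norm <- c(1.0, 1.0, 1.2, 1.15, 0.95, 0.97, 1.3, 1.25)
  ext <- phase_extrema(fixture_norm_traces("a", times, norm), prot)
  expect_equal(ext$baseline_mean, 1.0)
  expect_equal(ext$stimulus_max, 1.2)
  expect_equal(ext$repolarized_min, 0.95)
  expect_equal(ext$egf_max, 1.3)

  flat <- fixture_norm_traces("a", times, rep(1, 8))
  ext_flat <- phase_extrema(flat, prot)
  expect_true(all(unlist(ext_flat[, -1]) == 1))

  # requesting a role the protocol lacks is an error naming the role
  perf <- fixture_protocol()
  nt <- fixture_norm_traces("a", protocol_times(perf), rep(1, 45))
  expect_error(phase_extrema(nt, perf), "repolarized")
  ok <- phase_extrema(nt, perf, roles = c("baseline", "stimulus", "egf"))
  expect_named(ok, c("cell_id", "baseline_mean", "stimulus_max", "egf_max"))
})

test_that("percent_erk is exactly invariant to gains, offsets, and reordering", {
  traces <- fixture_two_channel_traces()
  prot <- fixture_protocol()
  quant <- function(tr) {
    nt <- normalize_traces(compute_ratio(tr), c(8, 10))
    percent_erk(nt, prot)
  }
  ref <- quant(traces)

  # power-of-two per-channel gains leave percent_erk bitwise unchanged
  scaled <- dplyr::mutate(traces, cfp = cfp * 2, yfp = yfp * 0.5)
  expect_identical(quant(scaled)$percent_erk, ref$percent_erk)

  # arbitrary positive gains leave it unchanged to floating tolerance
  scaled2 <- dplyr::mutate(traces, cfp = cfp * 1.7, yfp = yfp * 0.33)
  expect_equal(quant(scaled2)$percent_erk, ref$percent_erk, tolerance = 1e-12)

  # reordering rows changes nothing
  shuffled <- traces[sample(nrow(traces)), ]
  expect_equal(
    dplyr::arrange(quant(shuffled), cell_id)$percent_erk,
    dplyr::arrange(ref, cell_id)$percent_erk
  )

  # shifting the time axis of trace and protocol together changes nothing
  shifted <- dplyr::mutate(traces, time_min = time_min + 100)
  prot_shift <- perfusion_protocol(
    dplyr::mutate(prot$phases,
      start_min = start_min + 100, end_min = end_min + 100
    ),
    prot$frame_interval_min
  )
  nt_shift <- normalize_traces(compute_ratio(shifted), c(108, 110))
  expect_equal(percent_erk(nt_shift, prot_shift)$percent_erk, ref$percent_erk)

  # a global additive offset cancels exactly against the background ROIs
  ts_int <- dplyr::mutate(traces, cfp = round(cfp * 4), yfp = round(yfp * 4))
  r0 <- render_image_stack(ts_int, background_offset = 0, shot_noise = FALSE)
  r100 <- render_image_stack(ts_int, background_offset = 100, shot_noise = FALSE)
  t0 <- extract_cell_traces(r0$stack, r0$masks, r0$background_rois)
  t100 <- extract_cell_traces(r100$stack, r100$masks, r100$background_rois)
  expect_identical(quant(t0)$percent_erk, quant(t100)$percent_erk)
})
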