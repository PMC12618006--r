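test_that("nernst_potential matches the closed form and its invariants", {
  # equal concentrations force zero potential for any k, T
  for (k in c(1, 5, 145)) {
    expect_identical(nernst_potential(k, k, 310), 0)
  }
  # one decade of K+ is RT/F * ln(10): 59.16 mV at 298.15 K
  slope <- 1000 * 8.314462618 * 298.15 / 96485.33212 * log(10)
  expect_equal(nernst_potential(14.5, 145, 298.15), -slope, tolerance = 1e-12)
  expect_equal(slope, 59.16, tolerance = 0.01 / 59.16)
  # hand-evaluated closed form at body temperature
  expect_equal(nernst_potential(5, 145, 310.15),
    1000 * 8.314462618 * 310.15 / 96485.33212 * log(5 / 145),
    tolerance = 1e-12
  )
  expect_equal(nernst_potential(5, 145, 310.15), -90.0, tolerance = 0.001)
  # strictly increasing in k_out
  v <- nernst_potential(c(1, 2, 5, 15, 50, 145), 145)
  expect_true(all(diff(v) > 0))
  expect_error(nernst_potential(0), "positive")
  expect_error(nernst_potential(5, -1), "positive")
  expect_error(nernst_potential(5, 145, 0), "positive")
})

test_that("phase lookup uses half-open boundaries and rejects out-of-span times", {
  prot <- perfusion_protocol(tibble::tibble(
    start_min = c(0, 10, 30), end_min = c(10, 30, 40),
    role = c("baseline", "stimulus", "egf"), k_out_mM = c(5, 145, 5)
  ))
  expect_identical(phase_role_at(prot, 10), "stimulus") # switch frame -> new phase
  expect_identical(phase_role_at(prot, 9.99), "baseline")
  expect_identical(phase_role_at(prot, 0), "baseline")
  expect_identical(phase_role_at(prot, 39.999), "egf")
  expect_error(phase_at(prot, 45), "span")
  expect_error(phase_at(prot, 40), "span") # end itself is outside [0, 40)
  expect_error(phase_at(prot, -1), "span")
})

test_that("protocol construction enforces ordering, contiguity, and roles", {
  ok <- tibble::tibble(
    start_min = c(0, 10), end_min = c(10, 30),
    role = c("baseline", "stimulus"), k_out_mM = c(5, 145)
  )
  expect_s3_class(perfusion_protocol(ok), "perfusion_protocol")
  bad_order <- ok
  bad_order$start_min[2] <- 12 # gap
  expect_error(perfusion_protocol(bad_order), "phase 2")
  bad_span <- ok
  bad_span$end_min[1] <- 0
  expect_error(perfusion_protocol(bad_span), "phase 1")
  bad_role <- ok
  bad_role$role[2] <- "wash"
  expect_error(perfusion_protocol(bad_role), "wash")
  swapped <- tibble::tibble(
    start_min = c(0, 10), end_min = c(10, 30),
    role = c("stimulus", "baseline"), k_out_mM = c(145, 5)
  )
  expect_error(perfusion_protocol(swapped), "baseline")
})

test_that("predicted voltage series is piecewise constant with correct steps", {
  # clamp phases pass the commanded voltage through verbatim
  clamp <- clamp_protocol(v_step = -20)
  v <- predicted_voltage_series(clamp)
  expect_equal(unique(v$voltage_mV[v$time_min < 5]), -80)
  expect_equal(unique(v$voltage_mV[v$time_min >= 5 & v$time_min < 10]), -20)
  expect_equal(unique(v$voltage_mV[v$time_min >= 10]), -80)

  # perfusion at the intracellular concentration predicts 0 mV
  prot145 <- perfusion_protocol(tibble::tibble(
    start_min = 0, end_min = 10, role = "stimulus", k_out_mM = 145
  ))
  expect_true(all(predicted_voltage_series(prot145, k_in = 145)$voltage_mV == 0))

  # a 5K -> 15K switch at t = 10 steps by (RT/F) ln(3) ~ +28.2 mV
  prot <- perfusion_protocol(tibble::tibble(
    start_min = c(0, 10), end_min = c(10, 20),
    role = c("baseline", "stimulus"), k_out_mM = c(5, 15)
  ))
  v <- predicted_voltage_series(prot, k_in = 145, temperature = 298.15)
  step <- v$voltage_mV[v$time_min == 10] - v$voltage_mV[v$time_min == 9]
  expect_equal(step, 1000 * 8.314462618 * 298.15 / 96485.33212 * log(3),
    tolerance = 1e-12
  )
  expect_equal(step, 28.2, tolerance = 0.1)
  # piecewise constant: breakpoints only at the phase switch
  expect_identical(which(diff(v$voltage_mV) != 0), 10L)

  # a phase with neither concentration nor voltage is a specification error
  empty <- perfusion_protocol(tibble::tibble(
    start_min = 0, end_min = 10, role = "baseline"
  ))
  expect_error(predicted_voltage_series(empty), "phase 1")
})

test_that("protocol files round-trip through JSON and YAML with validation", {
  prot <- standard_perfusion_protocol(30)
  for (ext in c("json", "yaml")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_protocol(prot, path)
    back <- read_protocol(path)
    expect_equal(back$phases$start_min, prot$phases$start_min)
    expect_equal(back$phases$k_out_mM, prot$phases$k_out_mM)
    expect_equal(back$frame_interval_min, prot$frame_interval_min)
  }
  # missing key errors name the offending phase
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(phases = list(
      list(start_min = 0, end_min = 10, role = "baseline", k_out_mM = 5),
      list(start_min = 10, role = "stimulus", k_out_mM = 145)
    )),
    path,
    auto_unbox = TRUE
  )
  expect_error(read_protocol(path), "phase 2.*end_min")
})
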