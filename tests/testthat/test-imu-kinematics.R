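test_that("standing calibration subtracts the standing mean", {
  standing <- tibble::tibble(time_s = seq(0, 5, by = 0.01),
                             thigh_angle_deg = 2.3)
  series <- tibble::tibble(time_s = seq(0, 1, by = 0.01),
                           thigh_angle_deg = 32.3)
  out <- calibrate_standing(series, standing)
  expect_equal(out$thigh_angle_deg, rep(30.0, nrow(series)))
  # a series calibrated against itself is all zero
  self <- calibrate_standing(standing, standing)
  expect_equal(self$thigh_angle_deg, rep(0, nrow(standing)))
  short <- standing[1:5, ]
  expect_error(calibrate_standing(series, short),
               class = "gaitadapt_validation_error")
})

test_that("zero-phase low-pass preserves the passband and kills the stopband", {
  rate <- 400
  tt <- seq(0, 10 - 1 / rate, by = 1 / rate)
  amp_after <- function(f_hz) {
    x <- tibble::tibble(time_s = tt, thigh_angle_deg = sin(2 * pi * f_hz * tt))
    y <- lowpass_filter(x, 7)$thigh_angle_deg
    # amplitude via the Fourier coefficient at f_hz (edge 10% trimmed)
    core <- seq(round(0.1 * length(tt)), round(0.9 * length(tt)))
    2 * abs(mean(y[core] * exp(-2i * pi * f_hz * tt[core])))
  }
  expect_gt(amp_after(1), 0.99)   # < 1% attenuation at 1 Hz
  expect_lt(amp_after(50), 0.10)  # > 90% attenuation at 50 Hz
  # phase: zero-lag cross-correlation peak for the passband tone
  x <- tibble::tibble(time_s = tt, thigh_angle_deg = sin(2 * pi * tt))
  y <- lowpass_filter(x, 7)$thigh_angle_deg
  core <- 500:3500
  lags <- -5:5
  cc <- vapply(lags, function(l) cor(x$thigh_angle_deg[core], y[core + l]),
               numeric(1))
  expect_equal(lags[which.max(cc)], 0)
  # DC preserved exactly (to numerical tolerance)
  const <- tibble::tibble(time_s = tt, thigh_angle_deg = 12)
  expect_equal(lowpass_filter(const, 7)$thigh_angle_deg, rep(12, length(tt)),
               tolerance = 1e-8)
  expect_error(lowpass_filter(const, 200),
               class = "gaitadapt_validation_error")
})

test_that("events of a pure sinusoid match the analytic extrema", {
  rate <- 400
  tt <- seq(0, 22 - 1 / rate, by = 1 / rate)
  x <- tibble::tibble(time_s = tt,
                      thigh_angle_deg = 10 + 30 * sin(2 * pi * tt / 1.1))
  ev <- detect_gait_events(x)
  mhf <- dplyr::filter(ev, kind == "MHF")
  mhe <- dplyr::filter(ev, kind == "MHE")
  expect_equal(nrow(mhf), 20)
  expect_equal(diff(mhf$time_s), rep(1.1, 19), tolerance = 1.5 / rate)
  expect_equal(mhf$angle_deg, rep(40, 20), tolerance = 1e-3)
  expect_equal(mhe$angle_deg, rep(-20, nrow(mhe)), tolerance = 1e-3)
  # strict alternation
  expect_true(all(ev$kind[-1] != ev$kind[-nrow(ev)]))
  # constant signal: no events, empty result (not an error)
  const <- tibble::tibble(time_s = tt, thigh_angle_deg = 5)
  expect_equal(nrow(detect_gait_events(const)), 0)
})

test_that("cycle segmentation computes stride arithmetic", {
  ev <- tibble::tibble(
    time_s = c(0, 0.6, 1.1, 1.7, 2.2),
    angle_deg = c(40, -20, 40, -20, 40),
    kind = c("MHF", "MHE", "MHF", "MHE", "MHF"))
  cyc <- segment_cycles(ev)
  expect_equal(nrow(cyc), 2)
  expect_equal(cyc$stride_time_s, c(1.1, 1.1))
  expect_equal(cyc$step_freq_hz, c(1 / 1.1, 1 / 1.1))
  expect_equal(round(cyc$step_freq_hz[1], 4), 0.9091)
  # single MHF -> no cycles
  expect_equal(nrow(segment_cycles(ev[1:2, ])), 0)
  # a cycle without an intermediate trough is dropped
  ev2 <- ev[-2, ]
  expect_equal(nrow(segment_cycles(ev2)), 1)
  # exposure stamps accumulate within the block
  cyc2 <- segment_cycles(ev, exposure_start_min = 100, block_t0_s = 0)
  expect_equal(cyc2$exposure_min, 100 + c(0, 1.1) / 60)
})

test_that("noiseless generator blocks are recovered exactly by the pipeline", {
  cfg <- degenerate_config()
  pr <- generate_profile(cfg, seed = 1)
  thigh <- simulate_thigh_angle(pr, mini_schedule(walk_s = 60), seed = 3,
                                config = cfg)
  ev <- process_block(thigh)
  cyc <- segment_cycles(ev)
  expect_gt(nrow(cyc), 40)
  # stride times equal the generator period to one sample
  expect_true(all(abs(cyc$stride_time_s - pr$stride_period_mean) <=
                    1 / cfg$rate_hz + 1e-12))
  # calibrated angles match generator means within 0.1 deg
  expect_true(all(abs(cyc$mhf_deg - pr$mhf_mean) < 0.1))
  expect_true(all(abs(cyc$mhe_deg - pr$mhe_mean) < 0.1))
})

test_that("a known standing offset shifts detected angles by its negative", {
  cfg <- degenerate_config()
  pr <- generate_profile(cfg, seed = 1)
  pr$standing_offset <- 5
  thigh <- simulate_thigh_angle(pr, mini_schedule(walk_s = 30), seed = 3,
                                config = cfg)
  # without calibration, peaks sit 5 deg high; with it, at the true mean
  blk <- dplyr::filter(thigh, block_kind == "withsuit")
  raw_ev <- detect_gait_events(lowpass_filter(blk, 7))
  cal_ev <- process_block(thigh)
  raw_mhf <- mean(raw_ev$angle_deg[raw_ev$kind == "MHF"])
  cal_mhf <- mean(cal_ev$angle_deg[cal_ev$kind == "MHF"])
  expect_equal(raw_mhf - cal_mhf, 5, tolerance = 1e-2)
})

test_that("stride timing is robust to 0.5 deg white sensor noise", {
  cfg <- degenerate_config()
  cfg$sensor_noise_sd_deg <- 0.5
  pr <- generate_profile(cfg, seed = 1)
  deviations <- c()
  for (s in 1:3) {
    thigh <- simulate_thigh_angle(pr, mini_schedule(walk_s = 120), seed = s,
                                  config = cfg)
    cyc <- segment_cycles(process_block(thigh))
    deviations <- c(deviations, abs(cyc$stride_time_s - pr$stride_period_mean))
  }
  expect_gt(length(deviations), 250)
  frac_ok <- mean(deviations <= 1 / cfg$rate_hz + 1e-12)
  expect_gte(frac_ok, 0.99)
})

test_that("event alternation holds on noisy realistic blocks", {
  cfg <- cohort_config()
  pr <- generate_profile(cfg, seed = 21)
  thigh <- simulate_thigh_angle(pr, mini_schedule(walk_s = 90), seed = 8,
                                config = cfg)
  ev <- process_block(thigh)
  expect_gt(nrow(ev), 100)
  expect_true(all(ev$kind[-1] != ev$kind[-nrow(ev)]))
  cyc <- segment_cycles(ev)
  expect_true(all(cyc$stride_time_s > 0))
  expect_true(all(cyc$mhf_deg > cyc$mhe_deg))
  expect_equal(cyc$step_freq_hz, 1 / cyc$stride_time_s)
})
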