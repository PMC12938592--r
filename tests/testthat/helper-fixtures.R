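# Shared fixture builders. Everything is generated in code at test time.

# A degenerate (zero-spread) generator config: every subject identical,
# stride parameters exactly at their means when variances are zeroed too.
degenerate_config <- function(..., noise = FALSE) {
  cohort_config(
    body_mass_kg = c(73.42, 0), tau_min = c(202, 0),
    cost0_pct = c(100, 0), cost_ss_pct = c(91, 0),
    resting_power_w = c(85, 0), net_walk_wkg = c(3.3, 0),
    stride_period_s = c(1.1, 0), mhf_deg = c(30, 0), mhe_deg = c(-15, 0),
    var0_sf_hz2 = c(0, 0), varss_sf_hz2 = c(0, 0),
    var0_mhf_deg2 = c(0, 0), varss_mhf_deg2 = c(0, 0),
    var0_mhe_deg2 = c(0, 0), varss_mhe_deg2 = c(0, 0),
    tau_var_ratio = c(0.75, 0), standing_offset_deg = c(2, 0),
    day_drift_sd_pct = 0, breath_cv = 0,
    sensor_noise_sd_deg = if (noise) 0.3 else 0,
    ...
  )
}

# A short single-walking-block schedule for fast kinematic tests.
mini_schedule <- function(walk_s = 60, standing_s = 10, day = 1L) {
  tibble::tibble(
    day_index = day,
    block_index = 1:2,
    kind = c("standing", "withsuit"),
    duration_s = c(standing_s, walk_s),
    speed_m_s = 1.25
  )
}

# Toy labelled windows whose labels are a linear function of one feature.
toy_linear_windows <- function(subjects = paste0("T", 1:4), n = 120,
                               seed = 42) {
  set.seed(seed)
  dplyr::bind_rows(lapply(subjects, function(sid) {
    x <- runif(n, 0, 1)
    tibble::tibble(
      subject_id = sid, exposure_min = seq_len(n),
      var_sf_hz2 = x, var_mhf_deg2 = runif(n), var_mhe_deg2 = runif(n),
      adaptation_pct = 100 * x
    )
  }))
}

# Run one simulated walking block through the kinematic pipeline.
process_block <- function(thigh, cutoff_hz = 7) {
  standing <- dplyr::filter(thigh, block_kind == "standing")
  blk <- dplyr::filter(thigh, block_kind == "withsuit")
  blk |>
    calibrate_standing(standing) |>
    lowpass_filter(cutoff_hz) |>
    detect_gait_events()
}
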