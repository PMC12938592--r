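#' Generator settings for a synthetic exosuit-training cohort
#'
#' Returns the full set of tunable parameters used by [generate_profile()],
#' [simulate_thigh_angle()], [simulate_breath_series()] and
#' [generate_cohort()]. Sampled subject parameters are given as `c(mean, sd)`
#' pairs; a zero sd makes the draw degenerate (useful for noiseless tests).
#'
#' Defaults emulate a 6-day treadmill protocol: 40 min of with-suit exposure
#' per day at 1.25 m/s, metabolic cost decaying exponentially with cumulative
#' exposure (time constant around 202 min), and stride-to-stride variability
#' of step frequency and hip-angle extremes decaying on a proportional, faster
#' timescale. Initial/steady variance ratios are calibrated so the noiseless
#' Day-1 to Day-6 steady-state reductions land near 66% (step frequency),
#' 38% (peak flexion) and 43% (peak extension).
#'
#' @param n_days number of training days.
#' @param speed_m_s treadmill speed in m/s.
#' @param rate_hz IMU sampling rate in Hz.
#' @param body_mass_kg,tau_min,cost0_pct,cost_ss_pct,resting_power_w,
#'   net_walk_wkg,stride_period_s,mhf_deg,mhe_deg `c(mean, sd)` sampling pairs
#'   for per-subject physiology and kinematics. `tau_min` is the metabolic
#'   adaptation time constant in minutes of cumulative with-suit exposure;
#'   `cost0_pct`/`cost_ss_pct` the initial and asymptotic with-suit cost as a
#'   percentage of the same-day no-suit baseline.
#' @param var0_sf_hz2,varss_sf_hz2 `c(mean, sd)` initial and steady-state
#'   step-frequency variance (Hz^2).
#' @param var0_mhf_deg2,varss_mhf_deg2,var0_mhe_deg2,varss_mhe_deg2 same for
#'   the peak-flexion and peak-extension angle variances (deg^2).
#' @param tau_var_ratio `c(mean, sd)` for the ratio of the kinematic
#'   variability time constant to the metabolic one (`tau_var = ratio * tau`),
#'   encoding the shared-timescale hypothesis that variability stabilises in
#'   step with metabolic adaptation.
#' @param standing_offset_deg `c(mean, sd)` sensor mounting offset seen during
#'   quiet standing (removed downstream by standing calibration).
#' @param day_drift_sd_pct sd (in percent) of the multiplicative day-to-day
#'   metabolic baseline drift.
#' @param breath_cv coefficient of variation of multiplicative breath-by-breath
#'   noise on metabolic power.
#' @param sensor_noise_sd_deg sd of additive white angle sensor noise (deg).
#' @param rer fixed respiratory exchange ratio used to split target power into
#'   V̇O2 and V̇CO2.
#' @param simulate_nosuit_kinematics if `TRUE`, thigh-angle signals are also
#'   produced for no-suit walking blocks (the analysis only uses with-suit
#'   kinematics, so the default skips them).
#' @param variability_hump optional list `list(amp = c(sf, mhf, mhe), tau_min =
#'   <minutes>)` adding an early transient increase ("exploration hump") of the
#'   form `amp * (t/tau) * exp(1 - t/tau)` to each variance schedule; `NULL`
#'   (default) keeps the monotone exponential decay.
#'
#' @return a named list of class `cohort_config`.
#' @export
cohort_config <- function(n_days = 6,
                          speed_m_s = 1.25,
                          rate_hz = 400,
                          body_mass_kg = c(73.42, 9.56),
                          tau_min = c(202, 78),
                          cost0_pct = c(108, 3),
                          cost_ss_pct = c(91, 2),
                          resting_power_w = c(85, 8),
                          net_walk_wkg = c(3.3, 0.3),
                          stride_period_s = c(1.1, 0.04),
                          mhf_deg = c(30, 3),
                          mhe_deg = c(-15, 3),
                          var0_sf_hz2 = c(1.29e-3, 1.3e-4),
                          varss_sf_hz2 = c(1.0e-4, 1.0e-5),
                          var0_mhf_deg2 = c(2.37, 0.24),
                          varss_mhf_deg2 = c(1.0, 0.10),
                          var0_mhe_deg2 = c(2.23, 0.22),
                          varss_mhe_deg2 = c(0.80, 0.08),
                          tau_var_ratio = c(0.75, 0.04),
                          standing_offset_deg = c(2, 1),
                          day_drift_sd_pct = 3,
                          breath_cv = 0.05,
                          sensor_noise_sd_deg = 0.3,
                          rer = 0.85,
                          simulate_nosuit_kinematics = FALSE,
                          variability_hump = NULL) {
  cfg <- as.list(environment())
  if (tau_min[1] <= 0) {
    abort("`tau_min` must have a positive mean.", class = "gaitadapt_config_error")
  }
  pos_means <- c("body_mass_kg", "cost0_pct", "cost_ss_pct", "resting_power_w",
                 "net_walk_wkg", "stride_period_s", "tau_var_ratio")
  for (nm in pos_means) {
    if (cfg[[nm]][1] <= 0) {
      abort(paste0("`", nm, "` must have a positive mean."),
            class = "gaitadapt_config_error")
    }
  }
  structure(cfg, class = "cohort_config")
}

# Truncated-normal draw by resampling; `ok` is a predicate on the value.
draw_until <- function(pair, ok = function(x) TRUE, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    x <- rnorm(1, pair[1], pair[2])
    if (ok(x)) return(x)
  }
  abort("Could not sample a parameter satisfying its invariant.",
        class = "gaitadapt_config_error")
}

#' Sample one synthetic subject profile
#'
#' Draws subject-level physiology, gait geometry, and adaptation-curve
#' parameters from the distributions in `config`, resampling until all
#' profile invariants hold (positive time constants, `cost0 >= cost_ss`,
#' `var0 >= varss`, flexion peak above extension trough).
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; identical seeds give identical profiles.
#' @param subject_id label for the subject (default `"S1"`).
#' @return a one-row tibble with one column per profile parameter.
#' @export
generate_profile <- function(config = cohort_config(), seed = 1L,
                             subject_id = "S1") {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  tau <- draw_until(config$tau_min, function(x) x > 0)
  cost_ss <- draw_until(config$cost_ss_pct, function(x) x > 0)
  cost0 <- draw_until(config$cost0_pct, function(x) x >= cost_ss)
  mhe <- draw_until(config$mhe_deg)
  mhf <- draw_until(config$mhf_deg, function(x) x > mhe)
  vpair <- function(v0p, vssp) {
    vss <- draw_until(vssp, function(x) x >= 0)
    v0 <- draw_until(v0p, function(x) x >= vss)
    c(v0, vss)
  }
  sf <- vpair(config$var0_sf_hz2, config$varss_sf_hz2)
  vmhf <- vpair(config$var0_mhf_deg2, config$varss_mhf_deg2)
  vmhe <- vpair(config$var0_mhe_deg2, config$varss_mhe_deg2)
  ratio <- draw_until(config$tau_var_ratio, function(x) x > 0)
  tibble(
    subject_id = subject_id,
    body_mass = draw_until(config$body_mass_kg, function(x) x > 0),
    tau = tau,
    cost0 = cost0,
    cost_ss = cost_ss,
    resting_power = draw_until(config$resting_power_w, function(x) x > 0),
    net_walk_wkg = draw_until(config$net_walk_wkg, function(x) x > 0),
    stride_period_mean = draw_until(config$stride_period_s, function(x) x > 0),
    mhf_mean = mhf,
    mhe_mean = mhe,
    var0_sf = sf[1], varss_sf = sf[2],
    var0_mhf = vmhf[1], varss_mhf = vmhf[2],
    var0_mhe = vmhe[1], varss_mhe = vmhe[2],
    tau_var = ratio * tau,
    day_drift_sd = config$day_drift_sd_pct,
    breath_cv = config$breath_cv,
    standing_offset = draw_until(config$standing_offset_deg)
  )
}

#' Daily session schedule
#'
#' One training day: an initial quiet-standing block (resting metabolic
#' measurement), then eight test cycles of no-suit walking, rest, and
#' with-suit walking. With-suit walking totals 40 min; the rest after the
#' fourth cycle is extended to 5 min as the mid-session fatigue break.
#'
#' @param day_index integer day, 1 to 6.
#' @param speed_m_s treadmill speed (m/s).
#' @return a tibble with columns `day_index`, `block_index`, `kind`
#'   (`standing`, `nosuit`, `rest`, `withsuit`), `duration_s`, `speed_m_s`.
#' @export
default_schedule <- function(day_index, speed_m_s = 1.25) {
  if (length(day_index) != 1 || is.na(day_index) ||
      day_index != as.integer(day_index) || day_index < 1 || day_index > 6) {
    abort("`day_index` must be a single integer in 1..6.",
          class = "gaitadapt_validation_error")
  }
  kinds <- "standing"
  durs <- 300
  for (cycle in 1:8) {
    kinds <- c(kinds, "nosuit", "rest", "withsuit", "rest")
    durs <- c(durs, 120, 30, 300, if (cycle == 4) 300 else 30)
  }
  tibble(
    day_index = as.integer(day_index),
    block_index = seq_along(kinds),
    kind = kinds,
    duration_s = durs,
    speed_m_s = speed_m_s
  )
}

# Variance schedule v(t) = varss + (var0 - varss) * exp(-t / tau_var)
# (+ optional early transient hump), t in cumulative with-suit minutes.
variance_at <- function(t_min, var0, varss, tau_var, hump_amp = 0,
                        hump_tau = 20) {
  v <- varss + (var0 - varss) * exp(-t_min / tau_var)
  if (any(hump_amp != 0)) {
    v <- v + hump_amp * (t_min / hump_tau) * exp(1 - t_min / hump_tau)
  }
  v
}

# Metabolic cost schedule C(t) = cost_ss + (cost0 - cost_ss) * exp(-t / tau),
# in % of the same-day no-suit baseline.
cost_at <- function(t_min, cost0, cost_ss, tau) {
  cost_ss + (cost0 - cost_ss) * exp(-t_min / tau)
}

# Piecewise half-cosine stride waveform: each stride starts at a peak (MHF),
# descends to the trough (MHE) over `down_frac` of the cycle, then rises to
# the next stride's peak. Band-limited well below 7 Hz at normal cadence.
stride_waveform <- function(t, starts, periods, mhf, mhe, down_frac = 0.62) {
  k <- findInterval(t, starts)
  k[k < 1] <- 1L
  k[k > length(periods)] <- length(periods)
  p <- (t - starts[k]) / periods[k]
  p <- pmin(pmax(p, 0), 1)
  down <- p <= down_frac
  ang <- numeric(length(t))
  ang[down] <- mhe[k[down]] + (mhf[k[down]] - mhe[k[down]]) *
    (1 + cos(pi * p[down] / down_frac)) / 2
  up <- !down
  ku <- k[up]
  ang[up] <- mhe[ku] + (mhf[ku + 1L] - mhe[ku]) *
    (1 - cos(pi * (p[up] - down_frac) / (1 - down_frac))) / 2
  ang
}

simulate_walking_block <- function(profile, duration_s, exposure_start_min,
                                   accrues_exposure, rate_hz, noise_sd,
                                   hump) {
  pr <- as.list(profile)
  hamp <- if (is.null(hump)) c(0, 0, 0) else hump$amp
  htau <- if (is.null(hump)) 20 else hump$tau_min
  # draw strides sequentially until they cover the block
  n_max <- ceiling(duration_s / pr$stride_period_mean * 2) + 10L
  starts <- numeric(n_max)
  periods <- numeric(n_max)
  t_cum <- 0
  n <- 0L
  while (t_cum < duration_s && n < n_max) {
    e <- exposure_start_min + if (accrues_exposure) t_cum / 60 else 0
    v_sf <- variance_at(e, pr$var0_sf, pr$varss_sf, pr$tau_var, hamp[1], htau)
    f <- rnorm(1, 1 / pr$stride_period_mean, sqrt(v_sf))
    f <- max(f, 0.2)  # physical floor, never binds at realistic variances
    n <- n + 1L
    starts[n] <- t_cum
    periods[n] <- 1 / f
    t_cum <- t_cum + 1 / f
  }
  starts <- starts[seq_len(n)]
  periods <- periods[seq_len(n)]
  n <- length(periods)
  e_str <- exposure_start_min +
    if (accrues_exposure) starts / 60 else rep(0, n)
  v_mhf <- variance_at(e_str, pr$var0_mhf, pr$varss_mhf, pr$tau_var, hamp[2], htau)
  v_mhe <- variance_at(e_str, pr$var0_mhe, pr$varss_mhe, pr$tau_var, hamp[3], htau)
  # peaks sit at stride boundaries, so n+1 peak values are needed
  mhf <- rnorm(n + 1L, pr$mhf_mean, sqrt(c(v_mhf, v_mhf[n]))) + pr$standing_offset
  mhe <- rnorm(n, pr$mhe_mean, sqrt(v_mhe)) + pr$standing_offset
  tt <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
  ang <- stride_waveform(tt, starts, periods, mhf, mhe)
  if (noise_sd > 0) ang <- ang + rnorm(length(tt), 0, noise_sd)
  tibble(time_s = tt, thigh_angle_deg = ang)
}

#' Simulate the thigh-angle signal for one session
#'
#' Generates 400 Hz sagittal thigh-angle series for every walking block of a
#' session (with-suit blocks always; no-suit blocks only when requested), plus
#' the quiet-standing block. Per stride, the period, peak flexion (MHF) and
#' peak extension (MHE) are Gaussian draws whose variances follow the
#' subject's exponential variability-decay schedule evaluated at the stride's
#' cumulative with-suit exposure; within a stride the angle is a two-segment
#' half-cosine from peak to trough and back.
#'
#' @param profile a one-row profile tibble from [generate_profile()].
#' @param schedule a session schedule from [default_schedule()].
#' @param exposure_offset_min cumulative with-suit minutes before this session.
#' @param seed integer seed.
#' @param config a [cohort_config()] (sampling rate, sensor noise, flags).
#' @return a tibble with columns `block_index`, `block_kind`,
#'   `exposure_start_min`, `time_s` (within-block), `thigh_angle_deg`.
#' @export
simulate_thigh_angle <- function(profile, schedule, exposure_offset_min = 0,
                                 seed = 1L, config = cohort_config()) {
  set.seed(seed)
  out <- vector("list", nrow(schedule))
  exposure <- exposure_offset_min
  for (i in seq_len(nrow(schedule))) {
    kind <- schedule$kind[i]
    dur <- schedule$duration_s[i]
    block <- NULL
    if (kind == "standing") {
      tt <- seq(0, dur - 1 / config$rate_hz, by = 1 / config$rate_hz)
      block <- tibble(
        time_s = tt,
        thigh_angle_deg = profile$standing_offset +
          rnorm(length(tt), 0, config$sensor_noise_sd_deg)
      )
    } else if (kind == "withsuit" ||
               (kind == "nosuit" && config$simulate_nosuit_kinematics)) {
      block <- simulate_walking_block(
        profile, dur, exposure, accrues_exposure = (kind == "withsuit"),
        rate_hz = config$rate_hz, noise_sd = config$sensor_noise_sd_deg,
        hump = config$variability_hump)
    }
    if (!is.null(block)) {
      out[[i]] <- dplyr::mutate(block,
                                block_index = schedule$block_index[i],
                                block_kind = kind,
                                exposure_start_min = exposure,
                                .before = 1)
    }
    if (kind == "withsuit") exposure <- exposure + dur / 60
  }
  dplyr::bind_rows(out)
}

#' Simulate breath-by-breath gas exchange for one session
#'
#' Breath samples arrive every 2–5 s. The target gross metabolic power is
#' `resting_power` during standing and rest, `resting + net_walk * mass *
#' day_multiplier` during no-suit walking, and the same baseline scaled by the
#' subject's adaptation cost schedule `C(t)` (in % of baseline) during
#' with-suit walking, with `t` the cumulative with-suit exposure. V̇O2/V̇CO2
#' are chosen at a fixed respiratory exchange ratio so that the Brockway
#' equation reproduces the target power exactly; multiplicative log-normal
#' noise with coefficient of variation `breath_cv` is then applied.
#'
#' @inheritParams simulate_thigh_angle
#' @param day_multiplier multiplicative day-level drift factor applied to the
#'   net walking cost of both no-suit and with-suit blocks (so the daily
#'   no-suit normalization cancels it).
#' @return a tibble with columns `block_index`, `block_kind`, `time_s`
#'   (session clock), `exposure_min`, `vo2_ml_min`, `vco2_ml_min`.
#' @export
simulate_breath_series <- function(profile, schedule, exposure_offset_min = 0,
                                   day_multiplier = 1, seed = 1L,
                                   config = cohort_config()) {
  set.seed(seed)
  total <- sum(schedule$duration_s)
  # breath times: random 2-5 s gaps across the whole session
  gaps <- runif(ceiling(total / 2) + 10, 2, 5)
  bt <- cumsum(gaps)
  bt <- bt[bt < total]
  block_end <- cumsum(schedule$duration_s)
  block_start <- c(0, head(block_end, -1))
  idx <- findInterval(bt, block_start)
  exposure_at_block_start <- cumsum(
    c(0, head(ifelse(schedule$kind == "withsuit", schedule$duration_s, 0), -1))
  ) / 60 + exposure_offset_min
  kind <- schedule$kind[idx]
  expo <- exposure_at_block_start[idx] +
    ifelse(kind == "withsuit", (bt - block_start[idx]) / 60, 0)
  baseline_net <- profile$net_walk_wkg * profile$body_mass * day_multiplier
  power <- rep(profile$resting_power, length(bt))
  power[kind == "nosuit"] <- profile$resting_power + baseline_net
  ws <- kind == "withsuit"
  power[ws] <- profile$resting_power + baseline_net *
    cost_at(expo[ws], profile$cost0, profile$cost_ss, profile$tau) / 100
  cv <- profile$breath_cv
  if (cv > 0) {
    s <- sqrt(log(1 + cv^2))
    power <- power * rlnorm(length(power), -s^2 / 2, s)
  }
  rer <- config$rer
  vo2 <- 60 * power / (16.58 + 4.51 * rer)
  tibble(
    block_index = schedule$block_index[idx],
    block_kind = kind,
    time_s = bt,
    exposure_min = expo,
    vo2_ml_min = vo2,
    vco2_ml_min = rer * vo2
  )
}

#' Generate a complete synthetic cohort
#'
#' Samples `n_subjects` profiles, builds each day's schedule, draws the
#' day-to-day baseline drift multipliers, and derives deterministic
#' per-(subject, day) sub-seeds for the kinematic and breath signal
#' generators. Signals are produced on demand by [simulate_day()] from the
#' recorded sub-seeds, so regenerating any block is exactly reproducible.
#' The generator's own adaptation-curve parameters are kept as ground truth
#' for recovery tests.
#'
#' @param n_subjects number of subjects (at least 2; leave-one-subject-out
#'   needs two).
#' @param config a [cohort_config()].
#' @param seed master integer seed.
#' @return an object of class `gait_cohort`: a list with `profiles`,
#'   `schedules`, `day_multipliers`, `seeds`, `ground_truth`, and `config`.
#' @export
generate_cohort <- function(n_subjects = 5, config = cohort_config(),
                            seed = 1L) {
  if (n_subjects < 2) {
    abort("`n_subjects` must be at least 2 (LOSO needs two subjects).",
          class = "gaitadapt_validation_error")
  }
  set.seed(seed)
  profile_seeds <- sample.int(2^31 - 2, n_subjects)
  signal_seeds <- matrix(sample.int(2^31 - 2, n_subjects * config$n_days * 2),
                         ncol = 2)
  ids <- paste0("S", seq_len(n_subjects))
  profiles <- purrr::map2_dfr(
    profile_seeds, ids,
    function(s, id) generate_profile(config, seed = s, subject_id = id))
  set.seed(seed + 1L)
  drift <- tidyr::expand_grid(subject_id = ids,
                              day_index = seq_len(config$n_days)) |>
    mutate(day_multiplier = rnorm(dplyr::n(), 1, config$day_drift_sd_pct / 100))
  seeds <- tidyr::expand_grid(subject_id = ids,
                              day_index = seq_len(config$n_days)) |>
    mutate(thigh_seed = signal_seeds[, 1], breath_seed = signal_seeds[, 2])
  schedules <- purrr::map_dfr(seq_len(config$n_days), default_schedule,
                              speed_m_s = config$speed_m_s)
  structure(
    list(
      profiles = profiles,
      schedules = schedules,
      day_multipliers = drift,
      seeds = seeds,
      ground_truth = profiles |>
        select("subject_id", "cost0", "cost_ss", "tau", "tau_var"),
      config = config
    ),
    class = "gait_cohort"
  )
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat("<gait_cohort>", nrow(x$profiles), "subjects x", x$config$n_days,
      "days;", sum(x$schedules$duration_s[x$schedules$kind == "withsuit"] /
                     60 / x$config$n_days),
      "min with-suit walking per day at", x$config$speed_m_s, "m/s\n")
  invisible(x)
}

# Cumulative with-suit exposure (min) before a given day.
day_exposure_offset <- function(cohort, day_index) {
  per_day <- sum(cohort$schedules$duration_s[
    cohort$schedules$kind == "withsuit" &
      cohort$schedules$day_index == 1]) / 60
  per_day * (day_index - 1)
}

#' Regenerate one subject-day's signals from the cohort's recorded seeds
#'
#' @param cohort a [generate_cohort()] object.
#' @param subject_id subject label.
#' @param day_index day number.
#' @param what which signals to generate (`"thigh"`, `"breath"`, or both);
#'   skipping the 400 Hz kinematics makes metabolic-only passes much faster.
#' @return a list with `thigh` (angle samples for simulated blocks, standing
#'   included), `breath` (gas samples for all blocks), and `schedule`.
#' @export
simulate_day <- function(cohort, subject_id, day_index,
                         what = c("thigh", "breath")) {
  profile <- cohort$profiles[cohort$profiles$subject_id == subject_id, ]
  if (nrow(profile) != 1) {
    abort("Unknown subject id.", class = "gaitadapt_validation_error")
  }
  sched <- cohort$schedules |> filter(.data$day_index == !!day_index)
  sd_row <- cohort$seeds |>
    filter(.data$subject_id == !!subject_id, .data$day_index == !!day_index)
  mult <- cohort$day_multipliers |>
    filter(.data$subject_id == !!subject_id, .data$day_index == !!day_index) |>
    dplyr::pull(.data$day_multiplier)
  off <- day_exposure_offset(cohort, day_index)
  list(
    thigh = if ("thigh" %in% what)
      simulate_thigh_angle(profile, sched, off, seed = sd_row$thigh_seed,
                           config = cohort$config),
    breath = if ("breath" %in% what)
      simulate_breath_series(profile, sched, off, day_multiplier = mult,
                             seed = sd_row$breath_seed,
                             config = cohort$config),
    schedule = sched
  )
}

#' Write one subject-day's signals as plain CSV files
#'
#' Emits one `time_s, thigh_angle_deg` CSV per simulated block and one
#' `time_s, vo2_ml_min, vco2_ml_min` CSV for the session's breath data.
#'
#' @inheritParams simulate_day
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_day_csv <- function(cohort, subject_id, day_index, dir) {
  day <- simulate_day(cohort, subject_id, day_index)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (b in unique(day$thigh$block_index)) {
    blk <- day$thigh |> filter(.data$block_index == b)
    p <- file.path(dir, sprintf("%s_day%d_block%02d_%s_thigh.csv",
                                subject_id, day_index, b, blk$block_kind[1]))
    utils::write.csv(blk[, c("time_s", "thigh_angle_deg")], p,
                     row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, sprintf("%s_day%d_breath.csv", subject_id, day_index))
  utils::write.csv(
    day$breath[, c("time_s", "vo2_ml_min", "vco2_ml_min")], p,
    row.names = FALSE)
  invisible(c(paths, p))
}
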