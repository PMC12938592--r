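#' Calibrate a thigh-angle series against a quiet-standing trial
#'
#' Subtracts the mean standing angle so that 0 deg corresponds to the upright
#' thigh (flexion positive, extension negative). All non-angle columns are
#' preserved.
#'
#' @param series a tibble with columns `time_s` and `thigh_angle_deg`.
#' @param standing a tibble of quiet-standing samples with the same columns;
#'   must span at least 1 s.
#' @return `series` with `thigh_angle_deg` shifted by the standing mean.
#' @export
calibrate_standing <- function(series, standing) {
  stopifnot(all(c("time_s", "thigh_angle_deg") %in% names(series)),
            all(c("time_s", "thigh_angle_deg") %in% names(standing)))
  span <- diff(range(standing$time_s))
  if (!is.finite(span) || span < 1) {
    abort("Standing trial must span at least 1 s.",
          class = "gaitadapt_validation_error")
  }
  offset <- mean(standing$thigh_angle_deg)
  series$thigh_angle_deg <- series$thigh_angle_deg - offset
  series
}

# Infer the (uniform) sampling rate from the time stamps.
sampling_rate <- function(time_s) {
  dt <- median(diff(time_s))
  if (!is.finite(dt) || dt <= 0) {
    abort("Cannot infer a sampling rate from `time_s`.",
          class = "gaitadapt_validation_error")
  }
  1 / dt
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' ([signal::filtfilt()]), so event timing is not biased by filter delay.
#' The default 7 Hz cutoff removes sensor noise while preserving the primary
#' kinematic content of gait at 400 Hz.
#'
#' @param series a tibble with `time_s` and `thigh_angle_deg` (uniformly
#'   sampled).
#' @param cutoff_hz cutoff frequency; must be below the Nyquist frequency.
#' @return `series` with `thigh_angle_deg` replaced by the filtered signal.
#' @export
lowpass_filter <- function(series, cutoff_hz = 7) {
  rate <- sampling_rate(series$time_s)
  if (2 * cutoff_hz >= rate * (1 - 1e-9)) {
    abort(sprintf("Cutoff %.3g Hz is not below the Nyquist frequency %.3g Hz.",
                  cutoff_hz, rate / 2),
          class = "gaitadapt_validation_error")
  }
  bf <- signal::butter(4, cutoff_hz / (rate / 2), type = "low")
  x <- series$thigh_angle_deg
  # odd-reflection padding so the forward-backward pass settles before the
  # data start; signal::filtfilt alone leaves sizeable edge transients
  n <- length(x)
  p <- min(n - 1, ceiling(10 * rate / cutoff_hz))
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  yp <- as.numeric(signal::filtfilt(bf, xp))
  series$thigh_angle_deg <- yp[(p + 1):(p + n)]
  series
}

# Strictly alternating local extrema of x (indices + kind), with plateaus
# collapsed to their midpoint.
local_extrema <- function(x) {
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) < 2) return(tibble(index = integer(0), kind = character(0)))
  s <- sign(d[nz])
  turn <- which(diff(s) != 0)
  if (length(turn) == 0) return(tibble(index = integer(0), kind = character(0)))
  # extremum lies between nz[turn] and nz[turn + 1]; take plateau midpoint
  idx <- floor((nz[turn] + nz[turn + 1] + 1) / 2)
  kind <- ifelse(s[turn] > 0, "MHF", "MHE")
  tibble(index = as.integer(idx), kind = kind)
}

# Enforce alternation and prune low-amplitude peak/trough pairs: repeatedly
# remove the adjacent MHF/MHE pair with the smallest angle difference until
# every adjacent pair differs by at least `prominence`.
prune_extrema <- function(ext, x, prominence) {
  repeat {
    # collapse runs of the same kind to the most extreme member
    if (nrow(ext) == 0) return(ext)
    keep <- rep(TRUE, nrow(ext))
    run_start <- 1
    for (i in seq_len(nrow(ext))) {
      if (i == nrow(ext) || ext$kind[i + 1] != ext$kind[i]) {
        if (i > run_start) {
          vals <- x[ext$index[run_start:i]]
          best <- if (ext$kind[i] == "MHF") which.max(vals) else which.min(vals)
          keep[run_start:i] <- FALSE
          keep[run_start + best - 1] <- TRUE
        }
        run_start <- i + 1
      }
    }
    ext <- ext[keep, ]
    if (nrow(ext) < 2) return(ext)
    amp <- abs(diff(x[ext$index]))
    if (all(amp >= prominence)) return(ext)
    j <- which.min(amp)  # drop the weakest adjacent pair
    ext <- ext[-c(j, j + 1), ]
    if (nrow(ext) == 0) return(ext)
  }
}

#' Detect gait events (peak flexion and peak extension)
#'
#' Finds the per-stride maximum hip flexion (MHF, peaks) and maximum hip
#' extension (MHE, troughs) of a calibrated, low-pass-filtered thigh-angle
#' series. Events strictly alternate. Low-amplitude ripple is rejected by a
#' minimum peak-to-trough prominence, and peaks closer than half the median
#' stride period are merged (keeping the higher peak).
#'
#' Event times are refined to sub-sample precision by half-prominence
#' level-crossing interpolation; events whose flanks are truncated by the
#' series boundary (so the crossing is undefined) and events inside the
#' zero-phase filter's edge transient (the first and last `edge_guard_s` of
#' the series) are discarded.
#'
#' @param series a tibble with `time_s` and `thigh_angle_deg`.
#' @param min_prominence_deg minimum peak-to-adjacent-trough amplitude (deg).
#' @param min_period_frac minimum MHF-to-MHF spacing as a fraction of the
#'   median detected spacing.
#' @param edge_guard_s events closer than this to either end of the series
#'   are dropped (filter edge transients make them unreliable).
#' @param refine_events sub-sample event-time refinement (on by default);
#'   when disabled, event times are the sample times of the extrema.
#' @return a tibble with columns `time_s`, `angle_deg`, `kind` (`"MHF"` or
#'   `"MHE"`); zero rows if fewer than two flexion peaks are found.
#' @export
detect_gait_events <- function(series, min_prominence_deg = 5,
                               min_period_frac = 0.5,
                               edge_guard_s = 0.25,
                               refine_events = TRUE) {
  x <- series$thigh_angle_deg
  ext <- local_extrema(x)
  ext <- prune_extrema(ext, x, min_prominence_deg)
  if (nrow(ext) > 0 && edge_guard_s > 0) {
    tr <- range(series$time_s)
    tev <- series$time_s[ext$index]
    ext <- ext[tev >= tr[1] + edge_guard_s & tev <= tr[2] - edge_guard_s, ]
    ext <- prune_extrema(ext, x, min_prominence_deg)
  }
  # minimum-distance guard on peaks
  repeat {
    pk <- which(ext$kind == "MHF")
    if (length(pk) < 3) break
    spacing <- diff(series$time_s[ext$index[pk]])
    min_gap <- min_period_frac * median(spacing)
    bad <- which(spacing < min_gap)
    if (length(bad) == 0) break
    j <- bad[1]
    # drop the lower of the two close peaks plus the trough between them
    lo <- if (x[ext$index[pk[j]]] <= x[ext$index[pk[j + 1]]]) pk[j] else pk[j + 1]
    between <- intersect(seq(pk[j] + 1, pk[j + 1] - 1), which(ext$kind == "MHE"))
    drop <- c(lo, if (length(between)) between[which.max(x[ext$index[between]])])
    ext <- ext[-drop, ]
    ext <- prune_extrema(ext, x, min_prominence_deg)
  }
  if (sum(ext$kind == "MHF") < 2) {
    return(tibble(time_s = numeric(0), angle_deg = numeric(0),
                  kind = character(0)))
  }
  out <- tibble(time_s = series$time_s[ext$index],
                angle_deg = x[ext$index],
                kind = ext$kind)
  if (refine_events) {
    out$time_s <- refine_event_times(series$time_s, x, ext)
    out <- out[is.finite(out$time_s), ]
    if (sum(out$kind == "MHF") < 2) {
      return(tibble(time_s = numeric(0), angle_deg = numeric(0),
                    kind = character(0)))
    }
  }
  out
}

# Sub-sample peak-time refinement: midpoint of the two half-prominence level
# crossings flanking each extremum (linearly interpolated). The crossings sit
# on the steep flanks of the stride waveform, where the timing noise of the
# filtered signal is far smaller than at the flat peak itself, and the two
# flanks are distant enough to be nearly independent. A constant bias from
# waveform asymmetry cancels in peak-to-peak stride times. Events whose
# flanks never reach the level before the series boundary cannot be refined
# consistently with the rest and are returned as NA (the caller drops them).
refine_event_times <- function(time_s, x, ext) {
  tev <- time_s[ext$index]
  n <- length(x)
  for (k in seq_len(nrow(ext))) {
    i <- ext$index[k]
    sgn <- if (ext$kind[k] == "MHF") 1 else -1
    p <- sgn * x[i]
    # adjacent opposite-kind extrema bound the search and set the prominence
    lo_i <- if (k > 1) ext$index[k - 1] else 1L
    hi_i <- if (k < nrow(ext)) ext$index[k + 1] else n
    prom <- min(p - sgn * x[lo_i], p - sgn * x[hi_i])
    if (!is.finite(prom) || prom <= 0) {
      tev[k] <- NA_real_
      next
    }
    level <- p - prom / 2
    # walk outward to the first sample below the level on each side
    jl <- i
    while (jl > lo_i && sgn * x[jl] > level) jl <- jl - 1
    jr <- i
    while (jr < hi_i && sgn * x[jr] > level) jr <- jr + 1
    if (sgn * x[jl] > level || sgn * x[jr] > level) {
      tev[k] <- NA_real_
      next
    }
    tl <- cross_time(time_s, sgn * x, jl, level)
    tr <- cross_time(time_s, sgn * x, jr - 1L, level)
    tev[k] <- (tl + tr) / 2
  }
  tev
}

# Linear interpolation of the time at which s crosses `level` between samples
# j and j + 1.
cross_time <- function(time_s, s, j, level) {
  y0 <- s[j]; y1 <- s[j + 1]
  if (y1 == y0) return((time_s[j] + time_s[j + 1]) / 2)
  frac <- (level - y0) / (y1 - y0)
  time_s[j] + frac * (time_s[j + 1] - time_s[j])
}

#' Segment alternating events into gait cycles
#'
#' One cycle per consecutive pair of flexion peaks (MHF): stride time is the
#' peak-to-peak interval, the reported "step frequency" is its inverse,
#' and the extension angle is the trough between the two peaks. Cycles with a
#' missing intermediate trough are dropped.
#'
#' @param events event tibble from [detect_gait_events()].
#' @param exposure_start_min cumulative with-suit exposure (min) at the start
#'   of the block; each cycle is stamped with the exposure at its own start.
#' @param block_t0_s time of the block's first sample (defaults to the first
#'   event time's floor, 0 for block-local clocks).
#' @return a tibble with columns `start_time_s`, `stride_time_s`,
#'   `step_freq_hz`, `mhf_deg`, `mhe_deg`, `exposure_min`.
#' @export
segment_cycles <- function(events, exposure_start_min = 0, block_t0_s = 0) {
  empty <- tibble(start_time_s = numeric(0), stride_time_s = numeric(0),
                  step_freq_hz = numeric(0), mhf_deg = numeric(0),
                  mhe_deg = numeric(0), exposure_min = numeric(0))
  if (nrow(events) == 0) return(empty)
  pk <- which(events$kind == "MHF")
  if (length(pk) < 2) return(empty)
  out <- vector("list", length(pk) - 1)
  for (j in seq_len(length(pk) - 1)) {
    between <- seq(pk[j] + 1, pk[j + 1] - 1)
    troughs <- between[events$kind[between] == "MHE"]
    if (length(troughs) != 1) next  # malformed cycle: drop
    t0 <- events$time_s[pk[j]]
    stride <- events$time_s[pk[j + 1]] - t0
    out[[j]] <- tibble(
      start_time_s = t0,
      stride_time_s = stride,
      step_freq_hz = 1 / stride,
      mhf_deg = events$angle_deg[pk[j]],
      mhe_deg = events$angle_deg[troughs],
      exposure_min = exposure_start_min + (t0 - block_t0_s) / 60
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) empty else res
}

#' Extract gait cycles for a whole cohort
#'
#' Streams every simulated with-suit walking block of every subject-day
#' through the kinematic pipeline: standing calibration, 7 Hz zero-phase
#' low-pass filtering, event detection, and cycle segmentation.
#'
#' @param cohort a [generate_cohort()] object.
#' @param cutoff_hz low-pass cutoff (Hz).
#' @return a tibble of gait cycles with identification columns `subject_id`,
#'   `day_index`, `block_index` plus the columns of [segment_cycles()].
#' @export
extract_cycles <- function(cohort, cutoff_hz = 7) {
  out <- list()
  for (sid in cohort$profiles$subject_id) {
    for (d in seq_len(cohort$config$n_days)) {
      day <- simulate_day(cohort, sid, d, what = "thigh")
      standing <- day$thigh |> filter(.data$block_kind == "standing")
      walking <- day$thigh |> filter(.data$block_kind == "withsuit")
      for (b in unique(walking$block_index)) {
        blk <- walking |> filter(.data$block_index == b)
        blk_cal <- calibrate_standing(blk, standing)
        blk_f <- lowpass_filter(blk_cal, cutoff_hz)
        ev <- detect_gait_events(blk_f)
        cyc <- segment_cycles(ev, exposure_start_min = blk$exposure_start_min[1],
                              block_t0_s = blk$time_s[1])
        if (nrow(cyc) > 0) {
          out[[length(out) + 1]] <- cyc |>
            mutate(subject_id = sid, day_index = d, block_index = b,
                   .before = 1)
        }
      }
    }
  }
  dplyr::bind_rows(out)
}
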