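#' Metabolic power from gas exchange (Brockway)
#'
#' `P = 16.58 * (vo2 / 60) + 4.51 * (vco2 / 60)` watts, with V̇O2 and V̇CO2 in
#' ml/min (coefficients in W s/ml).
#'
#' @param vo2_ml_min,vco2_ml_min non-negative gas exchange rates (ml/min).
#' @return metabolic power in watts (vectorised).
#' @export
brockway_power <- function(vo2_ml_min, vco2_ml_min) {
  if (any(vo2_ml_min < 0, na.rm = TRUE) || any(vco2_ml_min < 0, na.rm = TRUE)) {
    abort("Gas exchange rates must be non-negative.",
          class = "gaitadapt_validation_error")
  }
  16.58 * (vo2_ml_min / 60) + 4.51 * (vco2_ml_min / 60)
}

#' Resting metabolic power from the quiet-standing block
#'
#' Mean Brockway power over the standing samples of a session's breath series.
#'
#' @param breath a breath tibble (from [simulate_breath_series()] or read from
#'   CSV) with `block_kind`, `vo2_ml_min`, `vco2_ml_min`.
#' @return resting power in watts.
#' @export
resting_power_estimate <- function(breath) {
  st <- breath |> filter(.data$block_kind == "standing")
  if (nrow(st) == 0) {
    abort("No standing samples to estimate resting power from.",
          class = "gaitadapt_validation_error")
  }
  mean(brockway_power(st$vo2_ml_min, st$vco2_ml_min))
}

#' Net metabolic cost of each walking block
#'
#' For every walking block: mean Brockway power over the block's final
#' `tail_minutes` (the respirometric steady-state tail), minus resting power,
#' divided by body mass. Blocks shorter than the tail yield `NA`.
#'
#' @param breath a session breath tibble with `block_index`, `block_kind`,
#'   `time_s`, `exposure_min`, `vo2_ml_min`, `vco2_ml_min`.
#' @param resting_power_w resting metabolic power (W).
#' @param body_mass_kg subject body mass (kg).
#' @param tail_minutes steady-state tail averaged per block (default 2 min).
#' @return a tibble with one row per walking block: `block_index`,
#'   `block_kind`, `exposure_min` (at the tail midpoint for with-suit blocks),
#'   `net_cost_wkg`, `n_breaths`.
#' @export
block_costs <- function(breath, resting_power_w, body_mass_kg,
                        tail_minutes = 2) {
  breath |>
    filter(.data$block_kind %in% c("nosuit", "withsuit")) |>
    group_by(.data$block_index, .data$block_kind) |>
    dplyr::group_modify(function(blk, key) {
      t0 <- min(blk$time_s)
      t1 <- max(blk$time_s)
      tl <- blk |> filter(.data$time_s >= t1 - tail_minutes * 60)
      # allow a small shortfall from breath-sampling granularity
      ok <- (t1 - t0) >= tail_minutes * 60 * 0.9 && nrow(tl) > 0
      tibble(
        exposure_min = if (nrow(tl)) mean(tl$exposure_min) else NA_real_,
        net_cost_wkg = if (!ok) NA_real_ else
          (mean(brockway_power(tl$vo2_ml_min, tl$vco2_ml_min)) -
             resting_power_w) / body_mass_kg,
        n_breaths = nrow(tl)
      )
    }) |>
    ungroup() |>
    select("block_index", "block_kind", "exposure_min", "net_cost_wkg",
           "n_breaths")
}

#' Normalize a with-suit cost to the daily no-suit baseline
#'
#' `100 * ws_cost / ns_cost` percent. Dividing by the same-day no-suit
#' baseline cancels day-to-day metabolic drift.
#'
#' @param ws_cost_wkg net with-suit cost (W/kg).
#' @param ns_cost_wkg positive net no-suit baseline cost (W/kg).
#' @return cost as a percentage of the daily baseline (vectorised).
#' @export
normalize_daily <- function(ws_cost_wkg, ns_cost_wkg) {
  if (any(!is.finite(ns_cost_wkg)) || any(ns_cost_wkg <= 0)) {
    abort("The no-suit baseline cost must be positive.",
          class = "gaitadapt_validation_error")
  }
  100 * ws_cost_wkg / ns_cost_wkg
}

#' Daily-normalized metabolic cost points for a whole cohort
#'
#' For every subject-day: estimates resting power from the standing block,
#' computes per-block net costs, averages the day's no-suit blocks into the
#' daily baseline, and normalizes each with-suit block's cost to it. One
#' point per with-suit block (8 per day, 48 per subject over 6 days).
#'
#' @param cohort a [generate_cohort()] object.
#' @param tail_minutes steady-state tail per block (default 2 min).
#' @return a tibble with `subject_id`, `day_index`, `block_index`,
#'   `exposure_min`, `cost_pct`.
#' @export
cohort_cost_points <- function(cohort, tail_minutes = 2) {
  out <- list()
  for (sid in cohort$profiles$subject_id) {
    mass <- cohort$profiles$body_mass[cohort$profiles$subject_id == sid]
    for (d in seq_len(cohort$config$n_days)) {
      day <- simulate_day(cohort, sid, d, what = "breath")
      rest_w <- resting_power_estimate(day$breath)
      costs <- block_costs(day$breath, rest_w, mass, tail_minutes)
      ns <- mean(costs$net_cost_wkg[costs$block_kind == "nosuit"],
                 na.rm = TRUE)
      ws <- costs |> filter(.data$block_kind == "withsuit",
                            is.finite(.data$net_cost_wkg))
      if (!is.finite(ns) || ns <= 0 || nrow(ws) == 0) next
      out[[length(out) + 1]] <- ws |>
        mutate(subject_id = sid, day_index = d,
               cost_pct = normalize_daily(.data$net_cost_wkg, ns)) |>
        select("subject_id", "day_index", "block_index", "exposure_min",
               "cost_pct")
    }
  }
  dplyr::bind_rows(out)
}

#' Fit the exponential adaptation curve to normalized cost points
#'
#' Nonlinear least squares of `C(t) = cost_ss + (cost0 - cost_ss) *
#' exp(-t / tau)` with the time constant bounded in (1, 1e4) min and
#' multistart initialisation; non-convergence is flagged, not thrown.
#'
#' @param costs a tibble with `exposure_min` and `cost_pct` (one subject).
#' @param tau_starts initialisation grid for tau (min).
#' @return an object of class `adaptation_curve` with `cost0`, `cost_ss`,
#'   `tau`, `r_squared`, `converged`, `n`, confidence bounds, and the raw fit.
#' @export
fit_adaptation_curve <- function(costs, tau_starts = c(30, 100, 200, 400)) {
  if (nrow(costs) < 6) {
    warn("Fewer than 6 cost points; adaptation fit may be unreliable.")
  }
  fit <- fit_exponential_decay(costs$exposure_min, costs$cost_pct,
                               tau_starts = tau_starts)
  structure(
    list(cost0 = unname(fit$estimates["y0"]),
         cost_ss = unname(fit$estimates["yss"]),
         tau = unname(fit$estimates["tau"]),
         conf_low = fit$conf_low, conf_high = fit$conf_high,
         r_squared = fit$r_squared, converged = fit$converged,
         n = fit$n, fit = fit$fit),
    class = "adaptation_curve")
}

#' @export
print.adaptation_curve <- function(x, ...) {
  cat(sprintf(
    "<adaptation_curve> cost0 = %.2f%%, cost_ss = %.2f%%, tau = %.1f min (R2 = %.3f%s)\n",
    x$cost0, x$cost_ss, x$tau, x$r_squared,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' @rdname fit_adaptation_curve
#' @param x an `adaptation_curve`.
#' @param ... unused.
#' @export
tidy.adaptation_curve <- function(x, ...) {
  tibble(
    term = c("cost0", "cost_ss", "tau"),
    estimate = c(x$cost0, x$cost_ss, x$tau),
    conf.low = unname(x$conf_low),
    conf.high = unname(x$conf_high)
  )
}

#' @rdname fit_adaptation_curve
#' @export
glance.adaptation_curve <- function(x, ...) {
  tibble(r.squared = x$r_squared, converged = x$converged, nobs = x$n,
         time_to_adaptation_min = tryCatch(time_to_adaptation(x),
                                           error = function(e) NA_real_))
}

#' Adaptation level at a given exposure
#'
#' The inverse of the fitted exponential cost decay:
#' `A(t) = 100 * (1 - exp(-t / tau))`, reaching 100% at the asymptotic
#' plateau. Strictly increasing, in `[0, 100)` for finite `t`.
#'
#' @param curve a converged [fit_adaptation_curve()] object (or any list with
#'   a positive `tau`).
#' @param t_min cumulative with-suit exposure, minutes (non-negative,
#'   vectorised).
#' @return adaptation level in percent.
#' @export
adaptation_level <- function(curve, t_min) {
  if (any(t_min < 0)) {
    abort("Exposure `t_min` must be non-negative.",
          class = "gaitadapt_validation_error")
  }
  if (!isTRUE(curve$converged)) {
    abort("Adaptation curve did not converge; no adaptation level defined.",
          class = "gaitadapt_validation_error")
  }
  100 * (1 - exp(-t_min / curve$tau))
}

#' Exposure time to reach the adaptation band
#'
#' Smallest exposure at which the fitted cost is within `band` (default 5%)
#' of the asymptotic value: `t* = tau * ln((cost0 - cost_ss) / (band *
#' cost_ss))`, or 0 if the curve starts inside the band. The alternative
#' convention — 95% of the decay amplitude completed, `t* = tau * ln(1/band)`
#' — is available via `mode = "amplitude"`.
#'
#' @param curve a converged [fit_adaptation_curve()] object.
#' @param band band width as a fraction of the asymptote (default 0.05).
#' @param mode `"asymptote"` (band relative to the asymptotic value, default)
#'   or `"amplitude"` (fraction of the decay amplitude remaining).
#' @return time in minutes.
#' @export
time_to_adaptation <- function(curve, band = 0.05,
                               mode = c("asymptote", "amplitude")) {
  mode <- match.arg(mode)
  if (!isTRUE(curve$converged)) {
    abort("Adaptation curve did not converge.",
          class = "gaitadapt_validation_error")
  }
  amp <- curve$cost0 - curve$cost_ss
  if (amp <= 0) return(0)
  thresh <- if (mode == "asymptote") band * curve$cost_ss else band * amp
  if (amp <= thresh) return(0)
  curve$tau * log(amp / thresh)
}

#' Ground-truth adaptation labels for variability windows
#'
#' Evaluates the metabolic adaptation level at each window's exposure stamp,
#' giving the continuous training target for the estimator.
#'
#' @param curve a converged [fit_adaptation_curve()] object.
#' @param windows a tibble from [build_feature_windows()].
#' @return `windows` with an added `adaptation_pct` column.
#' @export
ground_truth_labels <- function(curve, windows) {
  windows |> mutate(adaptation_pct = adaptation_level(curve, .data$exposure_min))
}

#' Fit per-subject adaptation curves and label a cohort's windows
#'
#' Convenience wrapper: computes daily-normalized cost points for every
#' subject ([cohort_cost_points()]), fits each subject's adaptation curve,
#' and attaches ground-truth adaptation labels to the feature windows.
#'
#' @param cohort a [generate_cohort()] object.
#' @param windows a tibble from [build_feature_windows()].
#' @param tail_minutes metabolic steady-state tail per block (default 2).
#' @return a list with `curves` (named list of `adaptation_curve` objects),
#'   `cost_points`, and `windows` (labelled).
#' @export
label_cohort <- function(cohort, windows, tail_minutes = 2) {
  points <- cohort_cost_points(cohort, tail_minutes)
  curves <- list()
  labelled <- list()
  for (sid in unique(windows$subject_id)) {
    pts <- points |> filter(.data$subject_id == sid)
    curve <- fit_adaptation_curve(pts)
    curves[[sid]] <- curve
    w <- windows |> filter(.data$subject_id == sid)
    if (isTRUE(curve$converged)) {
      labelled[[sid]] <- ground_truth_labels(curve, w)
    } else {
      warn(paste0("Adaptation curve for ", sid,
                  " did not converge; subject left unlabelled."))
    }
  }
  list(curves = curves, cost_points = points,
       windows = dplyr::bind_rows(labelled))
}
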