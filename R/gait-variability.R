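#' Windowed sample variance
#'
#' Variance over consecutive, non-overlapping windows of `window` values
#' (sample variance, divisor n - 1). Trailing values that do not fill a
#' complete window are dropped.
#'
#' @param values numeric vector of per-cycle values within one walking block.
#' @param window window length in cycles (default 10).
#' @return numeric vector of one variance per complete window (possibly empty).
#' @export
windowed_variance <- function(values, window = 10) {
  if (window < 2) {
    abort("`window` must be at least 2.", class = "gaitadapt_validation_error")
  }
  n_win <- length(values) %/% window
  if (n_win == 0) return(numeric(0))
  m <- matrix(values[seq_len(n_win * window)], nrow = window)
  apply(m, 2, var)
}

#' Build aligned variability windows from gait cycles
#'
#' Partitions each walking block's cycles into consecutive 10-cycle windows
#' (never spanning a block boundary or rest) and computes the three
#' variability features over the same cycles: step-frequency variance (Hz^2),
#' peak-flexion-angle variance and peak-extension-angle variance (deg^2).
#' Each window is stamped with the mean cumulative with-suit exposure of its
#' cycles.
#'
#' @param cycles a cycles tibble from [extract_cycles()] (columns
#'   `subject_id`, `day_index`, `block_index`, `step_freq_hz`, `mhf_deg`,
#'   `mhe_deg`, `exposure_min`).
#' @param window cycles per window (default 10).
#' @return a tibble with columns `subject_id`, `day_index`, `block_index`,
#'   `window_index` (chronological within subject), `exposure_min`,
#'   `var_sf_hz2`, `var_mhf_deg2`, `var_mhe_deg2`.
#' @export
build_feature_windows <- function(cycles, window = 10) {
  out <- cycles |>
    arrange(.data$subject_id, .data$day_index, .data$block_index,
            .data$start_time_s) |>
    group_by(.data$subject_id, .data$day_index, .data$block_index) |>
    mutate(.win = (dplyr::row_number() - 1L) %/% window,
           .n_in_block = dplyr::n()) |>
    filter(.data$.win < .data$.n_in_block %/% window) |>
    group_by(.data$subject_id, .data$day_index, .data$block_index,
             .data$.win) |>
    summarise(
      exposure_min = mean(.data$exposure_min),
      var_sf_hz2 = var(.data$step_freq_hz),
      var_mhf_deg2 = var(.data$mhf_deg),
      var_mhe_deg2 = var(.data$mhe_deg),
      .groups = "drop"
    ) |>
    arrange(.data$subject_id, .data$exposure_min) |>
    group_by(.data$subject_id) |>
    mutate(window_index = dplyr::row_number()) |>
    ungroup() |>
    select("subject_id", "day_index", "block_index", "window_index",
           "exposure_min", "var_sf_hz2", "var_mhf_deg2", "var_mhe_deg2")
  out
}

#' Per-session steady-state variability summary
#'
#' Mean of each variability feature over the windows whose exposure stamp
#' falls in the final `minutes` of that day's with-suit walking — the
#' steady-state tail used to compare sessions.
#'
#' @param windows a tibble from [build_feature_windows()].
#' @param minutes length of the end-of-session tail (default 3 min).
#' @return a tibble with one row per (subject, day): `var_sf_hz2`,
#'   `var_mhf_deg2`, `var_mhe_deg2`, `n_windows`. Days with no qualifying
#'   window get `NA` summaries.
#' @export
steady_state_summary <- function(windows, minutes = 3) {
  windows |>
    group_by(.data$subject_id, .data$day_index) |>
    summarise(
      .cut = max(.data$exposure_min) - minutes,
      var_sf_hz2 = mean(.data$var_sf_hz2[.data$exposure_min >= .data$.cut]),
      var_mhf_deg2 = mean(.data$var_mhf_deg2[.data$exposure_min >= .data$.cut]),
      var_mhe_deg2 = mean(.data$var_mhe_deg2[.data$exposure_min >= .data$.cut]),
      n_windows = sum(.data$exposure_min >= .data$.cut),
      .groups = "drop"
    ) |>
    select(-".cut")
}

#' Percent reduction between two session summaries
#'
#' `100 * (day1 - day6) / day1`; negative values indicate an increase.
#'
#' @param day1,day6 positive baseline value and comparison value.
#' @return percent reduction (vectorised).
#' @export
percent_reduction <- function(day1, day6) {
  if (any(!is.finite(day1)) || any(day1 <= 0)) {
    abort("`day1` must be positive.", class = "gaitadapt_validation_error")
  }
  100 * (day1 - day6) / day1
}

#' Fit an exponential decay to a variability indicator
#'
#' Nonlinear least squares of `v(t) = vss + (v0 - vss) * exp(-t / tau_var)`
#' over a subject's windows, with multistart initialisation over a grid of
#' time constants. Window variances carry multiplicative (constant-CV)
#' sampling noise — the sample variance of n cycles is chi-square distributed
#' around the true variance — so by default the model is fitted to `log(v)`,
#' which makes the noise homoskedastic; `scale = "linear"` fits the raw
#' values. Returns parameter estimates, 95% confidence intervals from the
#' parameter covariance, R-squared (on the fitting scale), and a convergence
#' flag; an unidentifiable fit (e.g. a constant series) is flagged rather
#' than thrown.
#'
#' @param windows a tibble from [build_feature_windows()] (a single subject's
#'   windows, or any tibble with `exposure_min` and the feature column).
#' @param feature one of `"sf"`, `"mhf"`, `"mhe"`.
#' @param tau_starts initialisation grid for the time constant (min).
#' @param scale `"log"` (default) or `"linear"` fitting scale.
#' @return an object of class `decay_fit` with elements `feature`,
#'   `estimates` (v0, vss, tau_var), `conf_low`, `conf_high`, `r_squared`,
#'   `converged`, `n`, and the underlying `nls` fit (or `NULL`).
#' @export
fit_indicator_decay <- function(windows, feature = c("sf", "mhf", "mhe"),
                                tau_starts = c(30, 100, 200, 400),
                                scale = c("log", "linear")) {
  feature <- match.arg(feature)
  scale <- match.arg(scale)
  col <- paste0("var_", feature, switch(feature, sf = "_hz2", "_deg2"))
  fit <- fit_exponential_decay(windows$exposure_min, windows[[col]],
                               tau_starts = tau_starts,
                               log_scale = scale == "log")
  structure(c(list(feature = feature), fit), class = "decay_fit")
}

# Shared exponential-decay fitter: y(t) = yss + (y0 - yss) * exp(-t / tau).
# Multistart nlsLM over tau_starts; returns the least-SSE converged fit.
# With log_scale = TRUE the residuals are taken on log(y) (requires y > 0),
# the right error model for multiplicative constant-CV noise.
fit_exponential_decay <- function(t, y, tau_starts = c(30, 100, 200, 400),
                                  tau_bounds = c(1, 1e4),
                                  log_scale = FALSE) {
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  n <- length(y)
  degenerate <- list(
    estimates = c(y0 = if (n) y[1] else NA_real_,
                  yss = if (n) mean(y) else NA_real_, tau = NA_real_),
    conf_low = c(y0 = NA_real_, yss = NA_real_, tau = NA_real_),
    conf_high = c(y0 = NA_real_, yss = NA_real_, tau = NA_real_),
    r_squared = NA_real_, converged = FALSE, n = n, fit = NULL)
  if (n < 4 || var(y) == 0 || diff(range(t)) == 0) return(degenerate)
  log_scale <- log_scale && all(y > 0)
  # robust starts: average of the earliest / latest tenth of the series
  ord <- order(t)
  head_n <- max(3, n %/% 10)
  y0_start <- mean(y[ord[seq_len(head_n)]])
  yss_start <- mean(y[ord[seq(n - head_n + 1, n)]])
  dat <- data.frame(t = t, y = y, ly = if (log_scale) log(y) else y)
  form <- if (log_scale) {
    ly ~ log(yss + (y0 - yss) * exp(-t / tau))
  } else {
    y ~ yss + (y0 - yss) * exp(-t / tau)
  }
  low <- if (log_scale) c(y0 = 0, yss = 0, tau = tau_bounds[1]) else
    c(y0 = -Inf, yss = -Inf, tau = tau_bounds[1])
  best <- NULL
  for (tau0 in tau_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        form,
        data = dat,
        start = list(y0 = y0_start, yss = yss_start, tau = tau0),
        lower = low,
        upper = c(y0 = Inf, yss = Inf, tau = tau_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) return(degenerate)
  fit <- best$fit
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  zc <- qt(0.975, df = max(n - 3, 1))
  yfit <- if (log_scale) log(y) else y
  sst <- sum((yfit - mean(yfit))^2)
  r2 <- 1 - best$sse / sst
  # tau pinned at a bound, or a CI wider than the estimate scale, signals an
  # unidentifiable decay
  tau_hat <- unname(est["tau"])
  identifiable <- tau_hat > tau_bounds[1] * 1.001 &&
    tau_hat < tau_bounds[2] * 0.999
  list(
    estimates = c(y0 = unname(est["y0"]), yss = unname(est["yss"]),
                  tau = tau_hat),
    conf_low = setNames(est - zc * se, c("y0", "yss", "tau")),
    conf_high = setNames(est + zc * se, c("y0", "yss", "tau")),
    r_squared = r2, converged = identifiable, n = n, fit = fit)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit: %s> v0 = %.4g, vss = %.4g, tau_var = %.4g min (R2 = %.3f%s)\n",
    x$feature, x$estimates["y0"], x$estimates["yss"], x$estimates["tau"],
    x$r_squared, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' @rdname fit_indicator_decay
#' @param x a `decay_fit` object.
#' @param ... unused.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(
    term = c("v0", "vss", "tau_var"),
    estimate = unname(x$estimates),
    conf.low = unname(x$conf_low),
    conf.high = unname(x$conf_high)
  )
}

#' @rdname fit_indicator_decay
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, converged = x$converged, nobs = x$n)
}
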