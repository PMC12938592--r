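#' Plot an adaptation curve with its cost points
#'
#' @param object an [fit_adaptation_curve()] object.
#' @param cost_points optional tibble with `exposure_min`, `cost_pct` to
#'   overlay the observed points.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.adaptation_curve <- function(object, cost_points = NULL, ...) {
  tmax <- if (!is.null(cost_points)) max(cost_points$exposure_min) else
    4 * object$tau
  grid <- tibble(
    exposure_min = seq(0, tmax, length.out = 200),
    cost_pct = cost_at(.data$exposure_min, object$cost0, object$cost_ss,
                       object$tau))
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$exposure_min,
                                          .data$cost_pct)) +
    ggplot2::geom_hline(yintercept = object$cost_ss, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Cumulative with-suit exposure (min)",
                  y = "Metabolic cost (% of daily no-suit baseline)")
  if (!is.null(cost_points)) {
    p <- p + ggplot2::geom_point(data = cost_points, alpha = 0.6)
  }
  p
}

#' Plot a variability-decay fit
#'
#' @param object a [fit_indicator_decay()] object.
#' @param windows optional window tibble to overlay observed variances.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.decay_fit <- function(object, windows = NULL, ...) {
  est <- object$estimates
  col <- paste0("var_", object$feature,
                switch(object$feature, sf = "_hz2", "_deg2"))
  tmax <- if (!is.null(windows)) max(windows$exposure_min) else
    4 * max(est["tau"], 60, na.rm = TRUE)
  grid <- tibble(
    exposure_min = seq(0, tmax, length.out = 200),
    v = est["yss"] + (est["y0"] - est["yss"]) *
      exp(-.data$exposure_min / est["tau"]))
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$exposure_min, .data$v)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Cumulative with-suit exposure (min)",
                  y = paste0(col, " (windowed variance)"))
  if (!is.null(windows)) {
    p <- p + ggplot2::geom_point(
      data = windows |> dplyr::rename(v = dplyr::all_of(col)),
      alpha = 0.4)
  }
  p
}

#' Plot streamed LOSO predictions against the reference adaptation curves
#'
#' @param report a [run_loso()] or [run_pipeline()] object.
#' @param band accuracy band to shade (percentage points).
#' @return a ggplot faceted by held-out subject.
#' @export
plot_predictions <- function(report, band = NULL) {
  preds <- if (inherits(report, "loso_report")) report$predictions else
    purrr::map_dfr(report$loso, function(r) r$predictions)
  band <- band %||% report$band
  ggplot2::ggplot(preds, ggplot2::aes(.data$exposure_min)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$adaptation_pct - band, 0),
                   ymax = pmin(.data$adaptation_pct + band, 100)),
      fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$adaptation_pct)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$adaptation_pred_pct),
                        size = 0.3, alpha = 0.5, colour = "steelblue") +
    ggplot2::facet_wrap(~test_subject) +
    ggplot2::labs(x = "Cumulative with-suit exposure (min)",
                  y = "Adaptation level (%)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

`%||%` <- function(a, b) if (is.null(a)) b else a
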