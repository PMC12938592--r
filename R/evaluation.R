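#' Leave-one-subject-out folds
#'
#' One fold per subject: that subject is the test set, all others train.
#'
#' @param subject_ids character vector of unique subject labels.
#' @return a tibble with list-column `train_ids` and column `test_id`.
#' @export
loso_folds <- function(subject_ids) {
  if (anyDuplicated(subject_ids)) {
    abort("Duplicate subject ids.", class = "gaitadapt_validation_error")
  }
  if (length(subject_ids) < 2) {
    abort("LOSO needs at least 2 subjects.",
          class = "gaitadapt_validation_error")
  }
  tibble(
    test_id = subject_ids,
    train_ids = purrr::map(subject_ids, function(s) setdiff(subject_ids, s))
  )
}

#' Band accuracy of adaptation predictions
#'
#' Percentage of windows whose prediction lies within `band` percentage
#' points of the reference (boundary inclusive).
#'
#' @param pred,ref equal-length numeric vectors (percent).
#' @param band half-width of the accuracy band in percentage points.
#' @return percent of windows within the band.
#' @export
band_accuracy <- function(pred, ref, band = 10) {
  if (length(pred) != length(ref) || length(pred) < 1) {
    abort("`pred` and `ref` must have equal, positive length.",
          class = "gaitadapt_validation_error")
  }
  100 * mean(abs(pred - ref) <= band)
}

#' Regression metrics for adaptation predictions
#'
#' Mean absolute error (percentage points), Pearson correlation, and
#' `R^2 = 1 - SSE/SST` (computable below zero; undefined correlation on a
#' constant reference is returned as `NA` with a warning).
#'
#' @param pred,ref equal-length numeric vectors, `n >= 3`.
#' @return a one-row tibble: `mae`, `pearson_r`, `r2`.
#' @export
regression_metrics <- function(pred, ref) {
  if (length(pred) != length(ref) || length(pred) < 3) {
    abort("`pred` and `ref` must have equal length of at least 3.",
          class = "gaitadapt_validation_error")
  }
  sst <- sum((ref - mean(ref))^2)
  r <- if (sd(ref) == 0 || sd(pred) == 0) {
    warn("Constant series: Pearson r undefined.")
    NA_real_
  } else {
    cor(pred, ref)
  }
  tibble(
    mae = mean(abs(pred - ref)),
    pearson_r = r,
    r2 = if (sst == 0) NA_real_ else 1 - sum((pred - ref)^2) / sst
  )
}

#' Paired t-test between Day-1 and Day-6 values
#'
#' Two-sided paired t-test ([stats::t.test()]) on per-subject differences.
#' Zero-variance differences are flagged (`degenerate = TRUE`) with `NA`
#' statistics instead of an error.
#'
#' @param day1,day6 equal-length per-subject value vectors (paired by
#'   position).
#' @return a one-row tibble: `t_stat`, `p_value`, `n`, `degenerate`.
#' @export
paired_ttest <- function(day1, day6) {
  if (length(day1) != length(day6) || length(day1) < 2) {
    abort("Paired samples must have equal length of at least 2.",
          class = "gaitadapt_validation_error")
  }
  d <- day1 - day6
  if (sd(d) == 0) {
    return(tibble(t_stat = if (all(d == 0)) 0 else NA_real_,
                  p_value = if (all(d == 0)) 1 else NA_real_,
                  n = length(d), degenerate = TRUE))
  }
  tt <- t.test(day1, day6, paired = TRUE)
  tibble(t_stat = unname(tt$statistic), p_value = tt$p.value,
         n = length(d), degenerate = FALSE)
}

#' Run leave-one-subject-out evaluation of the adaptation estimator
#'
#' For each fold: fits the feature scaler and trains the LSTM on the training
#' subjects' labelled windows, streams predictions over the held-out
#' subject's full chronological sequence, and scores them against that
#' subject's metabolic ground-truth labels (band accuracy, MAE, Pearson r,
#' R^2). Pooled metrics are unweighted means (and sds) over folds. A fold
#' whose training fails is flagged and skipped; the report is still produced.
#'
#' @param labelled_windows window tibble with features and `adaptation_pct`
#'   labels for all subjects.
#' @param config an [estimator_config()]; `config$seed` seeds each fold's
#'   weight initialisation (offset by the fold number).
#' @param band accuracy band in percentage points.
#' @param predictor optional override mapping `(model, windows)` to
#'   predictions, used for harness checks (e.g. an oracle predictor); by
#'   default the trained model's [predict_stream()].
#' @return an object of class `loso_report`: `per_fold` (tibble),
#'   `pooled` (tibble), `predictions` (per-window tibble).
#' @export
run_loso <- function(labelled_windows, config = estimator_config(),
                     band = 10, predictor = NULL) {
  ids <- unique(labelled_windows$subject_id)
  folds <- loso_folds(ids)
  fold_rows <- list()
  preds <- list()
  for (k in seq_len(nrow(folds))) {
    test_id <- folds$test_id[k]
    train <- labelled_windows |> filter(.data$subject_id != test_id)
    test <- labelled_windows |>
      filter(.data$subject_id == test_id) |>
      arrange(.data$exposure_min)
    fold_cfg <- config
    fold_cfg$seed <- config$seed + k
    result <- tryCatch({
      if (is.null(predictor)) {
        model <- train_estimator(train, fold_cfg)
        predict_stream(model, test)
      } else {
        predictor(train, test)
      }
    }, error = function(e) e)
    if (inherits(result, "error")) {
      warn(paste0("Fold ", test_id, " failed: ", conditionMessage(result)))
      fold_rows[[k]] <- tibble(test_subject = test_id, failed = TRUE,
                               band_accuracy = NA_real_, mae = NA_real_,
                               pearson_r = NA_real_, r2 = NA_real_,
                               n_windows = nrow(test))
      next
    }
    pr <- result$adaptation_pred_pct
    rf <- result$adaptation_pct
    metrics <- regression_metrics(pr, rf)
    fold_rows[[k]] <- tibble(
      test_subject = test_id, failed = FALSE,
      band_accuracy = band_accuracy(pr, rf, band),
      mae = metrics$mae, pearson_r = metrics$pearson_r, r2 = metrics$r2,
      n_windows = nrow(result))
    preds[[k]] <- result |> mutate(test_subject = test_id)
  }
  per_fold <- dplyr::bind_rows(fold_rows)
  ok <- per_fold |> filter(!.data$failed)
  pooled <- ok |>
    tidyr::pivot_longer(c("band_accuracy", "mae", "pearson_r", "r2"),
                        names_to = "metric", values_to = "value") |>
    group_by(.data$metric) |>
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              n_folds = dplyr::n(), .groups = "drop")
  structure(list(per_fold = per_fold, pooled = pooled,
                 predictions = dplyr::bind_rows(preds), band = band),
            class = "loso_report")
}

#' @export
print.loso_report <- function(x, ...) {
  ba <- x$pooled |> filter(.data$metric == "band_accuracy")
  mae <- x$pooled |> filter(.data$metric == "mae")
  cat(sprintf(
    "<loso_report> %d folds; band accuracy (±%g pp) %.1f ± %.1f%%; MAE %.2f pp\n",
    nrow(x$per_fold), x$band, ba$mean, ba$sd, mae$mean))
  invisible(x)
}

#' @rdname run_loso
#' @param x a `loso_report`.
#' @param ... unused.
#' @export
tidy.loso_report <- function(x, ...) x$per_fold

#' @rdname run_loso
#' @export
glance.loso_report <- function(x, ...) {
  x$pooled |>
    tidyr::pivot_wider(id_cols = "n_folds", names_from = "metric",
                       values_from = c("mean", "sd"))
}

#' Day-1 vs Day-6 indicator statistics
#'
#' Per-feature steady-state variability summaries on the first and last day,
#' per-subject percent reductions, their mean and sd, and the paired t-test
#' across subjects.
#'
#' @param windows a window tibble from [build_feature_windows()].
#' @param minutes steady-state tail length per day (default 3 min).
#' @return a tibble with one row per feature: `feature`, `mean_reduction_pct`,
#'   `sd_reduction_pct`, `t_stat`, `p_value`, `n`.
#' @export
indicator_day_stats <- function(windows, minutes = 3) {
  ss <- steady_state_summary(windows, minutes)
  days <- range(ss$day_index)
  purrr::map_dfr(c("sf", "mhf", "mhe"), function(f) {
    col <- paste0("var_", f, switch(f, sf = "_hz2", "_deg2"))
    wide <- ss |>
      select("subject_id", "day_index", dplyr::all_of(col)) |>
      tidyr::pivot_wider(names_from = "day_index", values_from =
                           dplyr::all_of(col), names_prefix = "d") |>
      dplyr::rename(day1 = paste0("d", days[1]), day6 = paste0("d", days[2]))
    red <- percent_reduction(wide$day1, wide$day6)
    tt <- paired_ttest(wide$day1, wide$day6)
    tibble(feature = f,
           mean_reduction_pct = mean(red), sd_reduction_pct = sd(red),
           t_stat = tt$t_stat, p_value = tt$p_value, n = tt$n)
  })
}

#' Day-1 vs Day-6 metabolic statistics
#'
#' Mean daily-normalized with-suit cost on the first and last day per
#' subject, the percent reduction, and the paired t-test.
#'
#' @param cost_points a tibble from [cohort_cost_points()].
#' @return a list: `per_subject` tibble (day1/day6 cost, reduction),
#'   `mean_reduction_pct`, `sd_reduction_pct`, `ttest`.
#' @export
metabolic_day_stats <- function(cost_points) {
  days <- range(cost_points$day_index)
  per_day <- cost_points |>
    filter(.data$day_index %in% days) |>
    group_by(.data$subject_id, .data$day_index) |>
    summarise(cost_pct = mean(.data$cost_pct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "day_index", values_from = "cost_pct",
                       names_prefix = "d") |>
    dplyr::rename(day1 = paste0("d", days[1]), day6 = paste0("d", days[2])) |>
    mutate(reduction_pct = percent_reduction(.data$day1, .data$day6))
  list(per_subject = per_day,
       mean_reduction_pct = mean(per_day$reduction_pct),
       sd_reduction_pct = sd(per_day$reduction_pct),
       ttest = paired_ttest(per_day$day1, per_day$day6))
}
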