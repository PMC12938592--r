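feature_cols <- c("var_sf_hz2", "var_mhf_deg2", "var_mhe_deg2")

#' Estimator configuration
#'
#' Settings for the recurrent (LSTM) adaptation estimator: a stack of
#' `num_layers` LSTM layers with `hidden_units` units each and a linear
#' output head, trained with Adam on mean-squared error, with early stopping
#' on a chronological validation tail held out from each training subject.
#'
#' @param hidden_units LSTM hidden size (default 128).
#' @param num_layers number of stacked LSTM layers (default 1).
#' @param learning_rate Adam step size (default 1e-3).
#' @param max_epochs training epoch budget (default 200).
#' @param patience early-stopping patience in epochs (default 20).
#' @param val_fraction fraction of each training subject's windows (the
#'   chronological tail) held out for validation; in (0, 0.5).
#' @param clip_norm global gradient-norm clip (0 disables).
#' @param seed integer seed governing weight initialisation.
#' @return a list of class `estimator_config`.
#' @export
estimator_config <- function(hidden_units = 128, num_layers = 1,
                             learning_rate = 1e-3, max_epochs = 200,
                             patience = 20, val_fraction = 0.2,
                             clip_norm = 5, seed = 1L) {
  if (hidden_units < 1) {
    abort("`hidden_units` must be positive.",
          class = "gaitadapt_validation_error")
  }
  if (num_layers < 1) {
    abort("`num_layers` must be at least 1.",
          class = "gaitadapt_validation_error")
  }
  if (val_fraction <= 0 || val_fraction >= 0.5) {
    abort("`val_fraction` must be in (0, 0.5).",
          class = "gaitadapt_validation_error")
  }
  structure(as.list(environment()), class = "estimator_config")
}

#' Fit a zero-mean/unit-variance feature scaler
#'
#' Means and standard deviations of the three variability features, computed
#' on training windows only (never the held-out subject). A constant feature
#' gets sd 1 with a warning so scaling stays defined.
#'
#' @param train_windows a tibble containing the feature columns
#'   `var_sf_hz2`, `var_mhf_deg2`, `var_mhe_deg2`.
#' @return an object of class `feature_scaler` (fields `mean`, `sd`).
#' @export
fit_scaler <- function(train_windows) {
  if (nrow(train_windows) < 2) {
    abort("Need at least 2 training windows to fit a scaler.",
          class = "gaitadapt_validation_error")
  }
  m <- vapply(train_windows[feature_cols], mean, numeric(1))
  s <- vapply(train_windows[feature_cols], sd, numeric(1))
  const <- !is.finite(s) | s == 0
  if (any(const)) {
    warn(paste("Constant feature(s):", paste(feature_cols[const],
                                             collapse = ", "),
               "- sd forced to 1."))
    s[const] <- 1
  }
  structure(list(mean = m, sd = s), class = "feature_scaler")
}

#' Apply a feature scaler
#'
#' @param windows a tibble with the feature columns.
#' @param scaler a [fit_scaler()] object.
#' @return `windows` with the feature columns standardised.
#' @export
scale_features <- function(windows, scaler) {
  stopifnot(inherits(scaler, "feature_scaler"))
  for (j in seq_along(feature_cols)) {
    col <- feature_cols[j]
    windows[[col]] <- (windows[[col]] - scaler$mean[j]) / scaler$sd[j]
  }
  windows
}

# Initial weights: uniform(-k, k), k = 1/sqrt(hidden); forget-gate bias +1.
init_weights <- function(n_features, config) {
  H <- config$hidden_units
  k <- 1 / sqrt(H)
  layers <- vector("list", config$num_layers)
  for (l in seq_len(config$num_layers)) {
    Dl <- if (l == 1) n_features else H
    W <- matrix(runif(4 * H * (Dl + H), -k, k), nrow = 4 * H)
    b <- rep(0, 4 * H)
    b[(H + 1):(2 * H)] <- 1
    layers[[l]] <- list(W = W, b = b)
  }
  list(layers = layers, w_out = runif(H, -k, k), b_out = 0)
}

# Split a labelled window tibble into per-subject chronological sequences.
as_sequences <- function(windows) {
  if (!all(feature_cols %in% names(windows))) {
    abort("Windows must contain the three variability feature columns.",
          class = "gaitadapt_validation_error")
  }
  windows |>
    arrange(.data$subject_id, .data$exposure_min) |>
    group_by(.data$subject_id) |>
    dplyr::group_split()
}

#' Train the recurrent adaptation estimator
#'
#' Sequence-to-sequence regression: for each training subject the full
#' chronological window sequence is one training sequence, with one
#' adaptation-level output per 10-cycle window. The recurrent state is
#' carried across the subject's entire sequence (blocks and days) and reset
#' between subjects. The feature scaler is fitted on the training windows;
#' labels are scaled to `[0, 1]` internally. The chronological tail
#' (`val_fraction`) of each training subject is excluded from the loss and
#' used for early stopping; the best-validation weights are returned.
#'
#' @param train_windows a labelled window tibble (columns `subject_id`,
#'   `exposure_min`, the three feature columns, `adaptation_pct` in
#'   `[0, 100]`).
#' @param config an [estimator_config()].
#' @return an object of class `adaptation_estimator` holding the scaler,
#'   weights, config, and training history.
#' @export
train_estimator <- function(train_windows, config = estimator_config()) {
  stopifnot(inherits(config, "estimator_config"))
  if (nrow(train_windows) == 0) {
    abort("No training windows.", class = "gaitadapt_validation_error")
  }
  if (!"adaptation_pct" %in% names(train_windows) ||
      any(!is.finite(train_windows$adaptation_pct)) ||
      any(train_windows$adaptation_pct < 0 | train_windows$adaptation_pct > 100)) {
    abort("`adaptation_pct` labels must be finite and within [0, 100].",
          class = "gaitadapt_validation_error")
  }
  scaler <- fit_scaler(train_windows)
  seqs <- as_sequences(scale_features(train_windows, scaler))
  xs <- list(); ys <- list(); tm <- list(); vm <- list()
  for (s in seq_along(seqs)) {
    sq <- seqs[[s]]
    Tn <- nrow(sq)
    n_val <- floor(config$val_fraction * Tn)
    mask_val <- c(rep(0, Tn - n_val), rep(1, n_val))
    xs[[s]] <- as.matrix(sq[feature_cols])
    ys[[s]] <- sq$adaptation_pct / 100
    tm[[s]] <- 1 - mask_val
    vm[[s]] <- mask_val
  }
  set.seed(config$seed)
  w0 <- init_weights(length(feature_cols), config)
  res <- .lstm_fit(xs, ys, tm, vm, w0,
                   lr = config$learning_rate,
                   max_epochs = as.integer(config$max_epochs),
                   patience = as.integer(config$patience),
                   clip_norm = config$clip_norm)
  if (isTRUE(res$diverged)) {
    abort("Training loss diverged (non-finite); try a lower learning rate.",
          class = "gaitadapt_training_error")
  }
  structure(
    list(weights = res$weights, scaler = scaler, config = config,
         history = tibble(epoch = seq_along(res$train_loss),
                          train_loss = as.numeric(res$train_loss),
                          val_loss = as.numeric(res$val_loss)),
         best_epoch = res$best_epoch,
         best_val_loss = res$best_val_loss,
         n_train_subjects = length(seqs)),
    class = "adaptation_estimator")
}

#' @export
print.adaptation_estimator <- function(x, ...) {
  cat(sprintf(
    "<adaptation_estimator> %d-layer LSTM, %d hidden units; trained %d epochs (best %d, val MSE %.4g)\n",
    x$config$num_layers, x$config$hidden_units, nrow(x$history),
    x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' @rdname train_estimator
#' @param x an `adaptation_estimator`.
#' @param ... unused.
#' @export
tidy.adaptation_estimator <- function(x, ...) {
  tidyr::pivot_longer(x$history, c("train_loss", "val_loss"),
                      names_to = "split", values_to = "mse") |>
    mutate(split = sub("_loss$", "", .data$split))
}

#' @rdname train_estimator
#' @export
glance.adaptation_estimator <- function(x, ...) {
  tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
         best_val_mse = x$best_val_loss,
         hidden_units = x$config$hidden_units,
         num_layers = x$config$num_layers,
         n_train_subjects = x$n_train_subjects)
}

#' Streamed adaptation predictions
#'
#' Runs the trained estimator over each subject's chronological window
#' sequence, carrying recurrent state across the whole sequence (reset
#' between subjects). Processing is causal: the estimate for a window uses
#' only that window and its predecessors. Outputs are clipped to `[0, 100]`.
#'
#' @param model a trained [train_estimator()] object.
#' @param windows a window tibble with `subject_id`, `exposure_min`, and the
#'   three feature columns (unscaled; the model's own scaler is applied).
#' @return `windows` with an added `adaptation_pred_pct` column, ordered
#'   chronologically within subjects.
#' @export
predict_stream <- function(model, windows) {
  stopifnot(inherits(model, "adaptation_estimator"))
  if (nrow(windows) == 0) {
    return(windows |> mutate(adaptation_pred_pct = numeric(0)))
  }
  seqs <- as_sequences(scale_features(windows, model$scaler))
  out <- purrr::map(seqs, function(sq) {
    x <- as.matrix(sq[feature_cols])
    if (ncol(x) != 3) {
      abort("Expected exactly 3 features.",
            class = "gaitadapt_validation_error")
    }
    y <- as.numeric(.lstm_forward(model$weights, x)) * 100
    sq$adaptation_pred_pct <- pmin(pmax(y, 0), 100)
    sq
  })
  dplyr::bind_rows(out)
}

#' @method predict adaptation_estimator
#' @rdname predict_stream
#' @param object a trained `adaptation_estimator`.
#' @param ... passed on (the window tibble as first argument).
#' @export
predict.adaptation_estimator <- function(object, ...) {
  predict_stream(object, ...)
}
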