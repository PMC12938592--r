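test_that("LOSO folds cover every subject exactly once and never leak", {
  ids <- paste0("S", 1:5)
  f <- loso_folds(ids)
  expect_equal(nrow(f), 5)
  expect_setequal(f$test_id, ids)
  for (k in seq_len(nrow(f))) {
    expect_false(f$test_id[k] %in% f$train_ids[[k]])
    expect_setequal(c(f$test_id[k], f$train_ids[[k]]), ids)
    expect_length(f$train_ids[[k]], 4)
  }
  expect_error(loso_folds(c("A", "A", "B")),
               class = "gaitadapt_validation_error")
  expect_error(loso_folds("A"), class = "gaitadapt_validation_error")
})

test_that("band accuracy handles boundaries and trivial cases", {
  ref <- c(10, 20, 30, 40)
  expect_equal(band_accuracy(ref, ref), 100)
  expect_equal(band_accuracy(ref + 10, ref), 100)   # boundary inclusive
  expect_equal(band_accuracy(ref - 10, ref), 100)
  expect_equal(band_accuracy(ref + 10.0001, ref), 0)
  expect_equal(band_accuracy(ref + 15, ref), 0)
  expect_equal(band_accuracy(c(10, 20, 45, 60), ref), 50)
  expect_equal(band_accuracy(ref + 3, ref, band = 2), 0)
  expect_error(band_accuracy(1:3, 1:4), class = "gaitadapt_validation_error")
})

test_that("band accuracy is monotone in the band width", {
  set.seed(4)
  ref <- runif(200, 0, 100)
  pred <- ref + rnorm(200, 0, 8)
  accs <- vapply(c(1, 2, 5, 10, 20, 50), function(b)
    band_accuracy(pred, ref, b), numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_equal(accs[length(accs)], 100)
})

test_that("regression metrics match hand-computed oracles", {
  ref <- c(3, 7, 1, 9, 4, 6, 2, 8, 5, 10)
  pred <- c(2.5, 8, 0, 10, 3, 6.5, 3, 7, 5.5, 9)
  m <- regression_metrics(pred, ref)
  # brute-force oracles
  expect_equal(m$mae, sum(abs(pred - ref)) / 10, tolerance = 1e-12)
  num <- sum((pred - mean(pred)) * (ref - mean(ref)))
  den <- sqrt(sum((pred - mean(pred))^2) * sum((ref - mean(ref))^2))
  expect_equal(m$pearson_r, num / den, tolerance = 1e-12)
  expect_equal(m$r2, 1 - sum((pred - ref)^2) / sum((ref - mean(ref))^2),
               tolerance = 1e-12)
  # pred = ref + c: MAE = |c|, r = 1, R2 = 1 - n c^2 / SST
  m2 <- regression_metrics(ref + 5, ref)
  expect_equal(m2$mae, 5)
  expect_equal(m2$pearson_r, 1)
  sst <- sum((ref - mean(ref))^2)
  expect_equal(m2$r2, 1 - 10 * 25 / sst, tolerance = 1e-12)
  # perfect prediction
  m3 <- regression_metrics(ref, ref)
  expect_equal(unlist(m3), c(mae = 0, pearson_r = 1, r2 = 1))
  expect_warning(mc <- regression_metrics(rep(1, 5), rep(2, 5)), "Constant")
  expect_true(is.na(mc$pearson_r))
})

test_that("the paired t-test matches the textbook formula", {
  # classic example: differences 1..5 -> t = mean(d)/(sd(d)/sqrt(n))
  day1 <- c(11, 12, 13, 14, 15)
  day6 <- c(10, 10, 10, 10, 10)
  tt <- paired_ttest(day1, day6)
  d <- day1 - day6
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(tt$t_stat, t_hand, tolerance = 1e-12)
  expect_equal(tt$t_stat, 4.242641, tolerance = 1e-6)
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 4)
  expect_equal(tt$p_value, p_hand, tolerance = 1e-12)
  expect_equal(tt$p_value, 0.0132, tolerance = 1e-2)
  # random fixtures against the hand formula
  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(7); b <- rnorm(7)
    tt <- paired_ttest(a, b)
    d <- a - b
    expect_equal(tt$t_stat, mean(d) / (sd(d) / sqrt(7)), tolerance = 1e-9)
    expect_equal(tt$p_value, 2 * stats::pt(-abs(tt$t_stat), df = 6),
                 tolerance = 1e-9)
    # antisymmetry
    rev <- paired_ttest(b, a)
    expect_equal(rev$t_stat, -tt$t_stat, tolerance = 1e-12)
    expect_equal(rev$p_value, tt$p_value, tolerance = 1e-12)
  }
  # degenerate cases flagged rather than thrown
  z <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_true(z$degenerate)
  expect_equal(z$t_stat, 0)
  expect_equal(z$p_value, 1)
  s <- paired_ttest(c(2, 3, 4), c(1, 2, 3))  # constant non-zero differences
  expect_true(s$degenerate)
  expect_true(is.na(s$t_stat))
})

test_that("an oracle predictor scores perfectly and constant-50 as computed", {
  w <- toy_linear_windows(subjects = paste0("S", 1:3), n = 150)
  oracle <- function(train, test) {
    dplyr::mutate(test, adaptation_pred_pct = adaptation_pct)
  }
  rep_o <- run_loso(w, predictor = oracle)
  expect_equal(rep_o$per_fold$band_accuracy, rep(100, 3))
  expect_equal(rep_o$per_fold$mae, rep(0, 3))
  expect_false(any(rep_o$per_fold$failed))
  const50 <- function(train, test) {
    dplyr::mutate(test, adaptation_pred_pct = 50)
  }
  rep_c <- suppressWarnings(run_loso(w, predictor = const50))
  # labels are 100*U(0,1); |50 - label| <= 10 iff label in [40, 60]
  expect_equal(rep_c$per_fold$band_accuracy,
               vapply(paste0("S", 1:3), function(s) {
                 lab <- w$adaptation_pct[w$subject_id == s]
                 100 * mean(lab >= 40 & lab <= 60)
               }, numeric(1)),
               ignore_attr = TRUE)
  expect_equal(rep_c$per_fold$mae,
               vapply(paste0("S", 1:3), function(s) {
                 mean(abs(50 - w$adaptation_pct[w$subject_id == s]))
               }, numeric(1)),
               ignore_attr = TRUE)
})

test_that("run_loso trains real models over a small two-subject problem", {
  w <- toy_linear_windows(subjects = c("A", "B"), n = 80)
  cfg <- estimator_config(hidden_units = 8, max_epochs = 30, patience = 30,
                          seed = 7)
  rep <- run_loso(w, cfg)
  expect_s3_class(rep, "loso_report")
  expect_equal(nrow(rep$per_fold), 2)
  expect_setequal(rep$per_fold$test_subject, c("A", "B"))
  expect_false(any(rep$per_fold$failed))
  expect_equal(rep$per_fold$n_windows, c(80, 80))
  expect_equal(nrow(rep$predictions), 160)
  # pooled table covers the four metrics
  expect_setequal(rep$pooled$metric,
                  c("band_accuracy", "mae", "pearson_r", "r2"))
  expect_true(all(rep$pooled$n_folds == 2))
  # glance/tidy are well formed
  expect_equal(nrow(tidy(rep)), 2)
  expect_equal(nrow(glance(rep)), 1)
  # determinism: same config seed -> identical report
  rep2 <- run_loso(w, cfg)
  expect_identical(rep$per_fold, rep2$per_fold)
})

test_that("day statistics reproduce known reductions on constructed data", {
  # two subjects, two days, constant within-day variances
  mk <- function(sid, day, v) tibble::tibble(
    subject_id = sid, day_index = day, block_index = 1, window_index = 1:5,
    exposure_min = seq(32, 40, by = 2),
    var_sf_hz2 = v, var_mhf_deg2 = v / 2, var_mhe_deg2 = v / 4)
  w <- dplyr::bind_rows(
    mk("S1", 1, 1.0), mk("S1", 6, 0.336),
    mk("S2", 1, 2.0), mk("S2", 6, 0.672))
  st <- indicator_day_stats(w, minutes = 3)
  expect_equal(nrow(st), 3)
  expect_equal(st$mean_reduction_pct, rep(66.4, 3), tolerance = 1e-9)
  expect_equal(st$sd_reduction_pct, rep(0, 3), tolerance = 1e-9)
  # metabolic day stats on constructed cost points
  cp <- tidyr::expand_grid(subject_id = c("S1", "S2"),
                           day_index = c(1, 6), block_index = 1:4) |>
    dplyr::mutate(exposure_min = block_index * 5,
                  cost_pct = ifelse(day_index == 1, 100, 91))
  ms <- metabolic_day_stats(cp)
  expect_equal(ms$mean_reduction_pct, 9)
  expect_equal(ms$sd_reduction_pct, 0)
  expect_true(ms$ttest$degenerate)  # identical differences across subjects
})
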