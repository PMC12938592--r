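test_that("Brockway power matches the standard coefficients", {
  expect_equal(brockway_power(0, 0), 0)
  expect_equal(brockway_power(240, 192), 16.58 * 4 + 4.51 * 3.2)
  expect_equal(brockway_power(240, 192), 80.752)
  # linearity
  expect_equal(brockway_power(480, 384), 2 * brockway_power(240, 192))
  expect_error(brockway_power(-1, 0), class = "gaitadapt_validation_error")
})

test_that("block costs recover known generator targets", {
  cfg <- degenerate_config()
  pr <- generate_profile(cfg, seed = 1)
  sch <- default_schedule(1)
  br <- simulate_breath_series(pr, sch, seed = 2, config = cfg)
  rest <- resting_power_estimate(br)
  expect_equal(rest, pr$resting_power, tolerance = 1e-9)
  costs <- block_costs(br, rest, pr$body_mass, tail_minutes = 2)
  # no-suit blocks: net cost equals the profile's baseline exactly
  ns <- dplyr::filter(costs, block_kind == "nosuit")
  expect_equal(nrow(ns), 8)
  expect_equal(ns$net_cost_wkg, rep(pr$net_walk_wkg, 8), tolerance = 1e-9)
  # constant power equal to resting -> zero net cost
  br_rest <- dplyr::mutate(br, block_kind = dplyr::if_else(
    block_kind == "standing", "nosuit", block_kind))
  vo2_rest <- 60 * pr$resting_power / (16.58 + 4.51 * 0.85)
  br0 <- dplyr::mutate(br_rest, vo2_ml_min = vo2_rest,
                       vco2_ml_min = 0.85 * vo2_rest)
  c0 <- block_costs(dplyr::filter(br0, block_kind == "nosuit"),
                    pr$resting_power, pr$body_mass)
  expect_equal(c0$net_cost_wkg, rep(0, nrow(c0)), tolerance = 1e-9)
  # a synthetic block with known target net power
  expect_equal(250 / 73.42, 3.405, tolerance = 1e-3)
})

test_that("daily normalization cancels baseline drift", {
  expect_equal(normalize_daily(3.3, 3.3), 100)
  expect_equal(normalize_daily(0.91 * 3.3, 3.3), 91)
  expect_equal(normalize_daily(1.07 * 2, 2), normalize_daily(1.07 * 3, 3))
  expect_error(normalize_daily(1, 0), class = "gaitadapt_validation_error")
})

test_that("cost points from a noiseless cohort recover the generator curve", {
  cfg <- degenerate_config()
  co <- generate_cohort(2, cfg, seed = 5)
  pts <- cohort_cost_points(co)
  expect_equal(nrow(pts), 2 * 6 * 8)  # 8 with-suit blocks x 6 days x 2 subjects
  gt <- co$ground_truth[1, ]
  s1 <- dplyr::filter(pts, subject_id == "S1")
  expected <- gt$cost_ss + (gt$cost0 - gt$cost_ss) *
    exp(-s1$exposure_min / gt$tau)
  # tail averaging of a within-block decay leaves only a tiny bias
  expect_equal(s1$cost_pct, expected, tolerance = 1e-4)
  fit <- fit_adaptation_curve(s1)
  expect_true(fit$converged)
  expect_lt(abs(fit$tau - gt$tau) / gt$tau, 0.01)
})

test_that("adaptation-curve fitting is self-consistent on exact points", {
  tt <- seq(0, 240, length.out = 48)
  pts <- tibble::tibble(exposure_min = tt,
                        cost_pct = 91 + (100 - 91) * exp(-tt / 202))
  fit <- fit_adaptation_curve(pts)
  expect_true(fit$converged)
  expect_equal(fit$cost0, 100, tolerance = 1e-6)
  expect_equal(fit$cost_ss, 91, tolerance = 1e-6)
  expect_equal(fit$tau, 202, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # constant series flagged, not thrown
  fitc <- fit_adaptation_curve(tibble::tibble(exposure_min = tt,
                                              cost_pct = 95))
  expect_false(fitc$converged)
  td <- tidy(fit)
  expect_equal(td$term, c("cost0", "cost_ss", "tau"))
})

test_that("tau is recovered from noisy cost points (Monte Carlo)", {
  # 5% CV lives at the breath level; each cost point is a 2-min block-tail
  # average over ~34 breaths (one every ~3.5 s), so point noise ~ 5%/sqrt(34)
  true_tau <- 150
  n_breaths <- 34
  errs <- vapply(1:20, function(rep) {
    set.seed(rep)
    tt <- seq(2.5, 240, length.out = 48)
    true_cost <- 91 + (108 - 91) * exp(-tt / true_tau)
    s <- sqrt(log(1 + 0.05^2))
    cost <- vapply(true_cost, function(ct) {
      mean(ct * rlnorm(n_breaths, -s^2 / 2, s))
    }, numeric(1))
    fit <- fit_adaptation_curve(tibble::tibble(exposure_min = tt,
                                               cost_pct = cost))
    abs(fit$tau - true_tau) / true_tau
  }, numeric(1))
  expect_lt(median(errs), 0.20)
})

test_that("adaptation level follows its closed form and is monotone", {
  curve <- list(cost0 = 100, cost_ss = 91, tau = 202, converged = TRUE)
  expect_equal(adaptation_level(curve, 0), 0)
  expect_equal(adaptation_level(curve, 202), 100 * (1 - exp(-1)))
  expect_equal(round(adaptation_level(curve, 202), 3), 63.212)
  expect_equal(adaptation_level(curve, 3 * 202), 95.021, tolerance = 1e-3)
  tt <- seq(0, 1000, by = 7)
  aa <- adaptation_level(curve, tt)
  expect_true(all(diff(aa) > 0))
  expect_true(all(aa >= 0 & aa < 100))
  expect_error(adaptation_level(curve, -1),
               class = "gaitadapt_validation_error")
  expect_error(adaptation_level(list(converged = FALSE, tau = 100), 10),
               class = "gaitadapt_validation_error")
})

test_that("time to adaptation follows the band definition", {
  curve <- list(cost0 = 100, cost_ss = 91, tau = 202, converged = TRUE)
  t_star <- time_to_adaptation(curve)
  expect_equal(t_star, 202 * log(9 / 4.55))
  expect_equal(t_star, 137.8, tolerance = 0.05)
  # already inside the band -> 0
  shallow <- list(cost0 = 92, cost_ss = 91, tau = 202, converged = TRUE)
  expect_equal(time_to_adaptation(shallow), 0)
  rising <- list(cost0 = 90, cost_ss = 91, tau = 202, converged = TRUE)
  expect_equal(time_to_adaptation(rising), 0)
  # linear in tau
  curve2 <- within(as.list(curve), tau <- 404)
  expect_equal(time_to_adaptation(curve2), 2 * t_star)
  # amplitude-fraction convention as configurable alternative
  expect_equal(time_to_adaptation(curve, mode = "amplitude"),
               202 * log(1 / 0.05))
})

test_that("ground-truth labels stamp windows with the adaptation level", {
  curve <- list(cost0 = 100, cost_ss = 91, tau = 202, converged = TRUE)
  w <- tibble::tibble(subject_id = "S1", exposure_min = c(0, 101, 202, 606),
                      var_sf_hz2 = 1, var_mhf_deg2 = 1, var_mhe_deg2 = 1)
  lw <- ground_truth_labels(curve, w)
  expect_equal(lw$adaptation_pct[1], 0)
  expect_equal(lw$adaptation_pct[3], 63.212, tolerance = 1e-3)
  expect_equal(lw$adaptation_pct[4], 95.021, tolerance = 1e-3)
  expect_true(all(diff(lw$adaptation_pct) > 0))
})
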