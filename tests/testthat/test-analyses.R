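test_that("signed circular errors wrap correctly on both task periods", {
  expect_equal(circular_error(350, 10), -20)
  expect_equal(circular_error(178, 5, period = 180), -7)
  expect_equal(circular_error(42, 42), 0)
  expect_equal(circular_error(190, 10), 180) # boundary maps to +period/2

  # antisymmetry off the boundary
  set.seed(2)
  r <- runif(200, 0, 360)
  t <- runif(200, 0, 360)
  off <- abs(circ_err <- circular_error(r, t)) != 180
  expect_equal(circ_err[off], -circular_error(t, r)[off])

  expect_error(circular_error(1, 2, period = -1),
               class = "tccwm_config_error")
})

test_that("circular variance matches the closed-form toy cases", {
  expect_equal(circular_variance(c(10, 10, 10)), 0)
  expect_equal(circular_variance(c(0, 120, 240)), 1)
  expect_equal(circular_variance(c(0, 0, 180)), 2 / 3)
})

test_that("binned absolute errors use half-open bins and plain averages", {
  # edge convention
  tr <- toy_trials(c(29, 30), c(29, 30))
  b <- bin_mean_abs_error(tr)
  expect_equal(b$bin[b$n > 0], c(1, 2))

  # all errors equal: every nonempty bin equals that error
  tr <- toy_trials(seq(0, 330, 30), (seq(0, 330, 30) + 7) %% 360)
  b <- bin_mean_abs_error(tr)
  expect_true(all(b$mean_abs_error[b$n > 0] == 7))

  # hand-computed means on a constructed 24-trial wheel
  targets <- rep(seq(0, 345, by = 15), each = 1)
  errors <- rep(c(2, 10), times = 12)
  tr <- toy_trials(targets, (targets + errors) %% 360)
  b <- bin_mean_abs_error(tr)
  expect_equal(b$n, rep(2L, 12))
  expect_equal(b$mean_abs_error, rep(6, 12)) # mean(2, 10) per bin
  expect_equal(b$bin_center, seq(15, 345, by = 30))

  expect_error(bin_mean_abs_error(tr, n_bins = 7),
               class = "tccwm_config_error")
})

test_that("rank correlations hit the exact extremes and reject tiny inputs", {
  h <- tibble::tibble(wheel = "w1", bin = 1:12,
                      mean_abs_error = c(5, 9, 3, 12, 7, 1, 8, 2, 11, 4, 6, 10))
  same <- spearman_difficulty(h, h)
  expect_equal(same$rho, 1)
  rev <- dplyr::mutate(h, mean_abs_error = -mean_abs_error)
  expect_equal(spearman_difficulty(h, rev)$rho, -1)

  # invariant to strictly monotone transforms
  mono <- dplyr::mutate(h, mean_abs_error = exp(mean_abs_error / 3))
  expect_equal(spearman_difficulty(h, mono)$rho, 1)

  expect_error(spearman_difficulty(h[1:2, ], h[1:2, ]),
               class = "tccwm_data_error")
})

test_that("noise ceilings collapse for deterministic data and straddle zero for noise", {
  # deterministic, distinct per-bin errors: every resample reproduces the
  # original ranking exactly
  targets <- rep(seq(7.5, 352.5, by = 15), each = 30)
  errors <- rep(seq(2, 25, length.out = 24), each = 30)
  tr <- toy_trials(targets, (targets + errors) %% 360)
  band <- noise_ceiling(tr, n_boot = 100, n_bins = 12, seed = 3)
  expect_equal(band$lower, 1)
  expect_equal(band$upper, 1)

  # pure guessing: the resample-vs-original correlation concentrates near
  # 1/sqrt(2) (a resample shares most trials with the original, so bin
  # noise is partly shared even without signal), well inside (0, 1)
  obs0 <- observer_spec(dprime = 0, kappa = 5)
  tr0 <- generate_trials(obs0, 2400, seed = 16)
  band0 <- noise_ceiling(tr0, n_boot = 200, seed = 4)
  expect_gt(band0$lower, -0.2)
  expect_lt(band0$upper, 1)
  expect_lt(band0$lower, band0$upper)

  # determinism
  band2 <- noise_ceiling(tr, n_boot = 100, n_bins = 12, seed = 3)
  expect_identical(band, band2)
})

test_that("condition-wise error summaries match their definitions", {
  tr <- toy_trials(rep(10, 50), rep(25, 50))
  e <- error_by_condition(tr, n_boot = 200, seed = 5)
  expect_equal(e$mean_abs_error, 15)
  expect_equal(e$lower, 15)
  expect_equal(e$upper, 15) # constant errors: zero-width interval

  # 90% level uses the 5th/95th bootstrap percentiles
  set.seed(6)
  tr <- toy_trials(rep(0, 400), runif(400, 0, 40))
  e <- error_by_condition(tr, n_boot = 500, ci_level = 0.90, seed = 7)
  expect_lt(e$lower, e$mean_abs_error)
  expect_gt(e$upper, e$mean_abs_error)
  expect_lt(e$upper - e$lower, 4 * sd(abs(circular_error(tr$response_deg,
                                                         tr$target_deg))) /
              sqrt(400) * 2)
})

test_that("bias curves report mean signed error per target bin", {
  targets <- rep(seq(0, 350, 10), each = 5)
  tr <- toy_trials(targets, (targets + 10) %% 360)
  bc <- bias_curve(tr)
  expect_true(all(bc$mean_error == 10))
  expect_s3_class(bc, "bias_curve")

  # an unbiased observer's curve hugs zero
  obs <- observer_spec(dprime = 2, kappa = 5)
  tr <- generate_trials(obs, 6000, seed = 17)
  bc <- bias_curve(tr)
  errs <- circular_error(tr$response_deg, tr$target_deg, 360)
  se <- sd(errs) / sqrt(min(bc$n))
  expect_true(all(abs(bc$mean_error) < 3 * se + 1e-9))
})

test_that("sine fits recover exact curves and canonicalise the sign ambiguity", {
  x <- seq(5, 355, by = 10)
  curve <- tibble::tibble(bin_center = x,
                          mean_error = 3 * sin(4 * x * pi / 180 +
                                                 20 * pi / 180))
  f <- fit_sine(curve)
  expect_equal(f$frequency, 4)
  expect_equal(f$amplitude, 3, tolerance = 1e-6)
  expect_equal(f$phase_deg, 20, tolerance = 1e-6)
  expect_lt(f$sse, 1e-12)

  # zero curve: amplitude 0, SSE 0
  f0 <- fit_sine(tibble::tibble(bin_center = x, mean_error = 0))
  expect_equal(f0$amplitude, 0)
  expect_equal(f0$sse, 0)

  # negated amplitude maps to the canonical (A, b + 180) representative
  fneg <- fit_sine(dplyr::mutate(curve, mean_error = -mean_error))
  expect_equal(fneg$amplitude, 3, tolerance = 1e-6)
  expect_equal(fneg$phase_deg, -160, tolerance = 1e-6)

  # residual SSE never exceeds the zero function's
  set.seed(8)
  for (i in 1:5) {
    y <- rnorm(36)
    f <- fit_sine(tibble::tibble(bin_center = seq(2.5, 177.5, 5),
                                 mean_error = y))
    expect_lte(f$sse, sum(y^2) + 1e-12)
  }

  expect_error(fit_sine(curve[1:3, ]), class = "tccwm_data_error")
  expect_error(fit_sine(curve, frequencies = c(3)),
               class = "tccwm_config_error")
})

test_that("inter-item variance analysis filters and correlates as designed", {
  set.seed(9)
  hues <- matrix(runif(300, 0, 360), ncol = 3)
  # structure preserving: responses are a common 60-degree rotation
  tr <- tibble::tibble(
    display = rep(1:100, each = 3),
    target_deg = as.vector(t(hues)),
    response_deg = (as.vector(t(hues)) + 60) %% 360)
  res <- interitem_variance_analysis(tr)
  expect_equal(res$n_included, 100) # every |error| = 60 > 45
  expect_gt(res$r, 0.999)

  # sub-threshold errors are excluded
  tr_small <- dplyr::mutate(tr, response_deg = (target_deg + 30) %% 360)
  expect_error(interitem_variance_analysis(tr_small),
               class = "tccwm_data_error")

  # displays must have exactly three probes
  expect_error(interitem_variance_analysis(tr[-1, ]),
               class = "tccwm_data_error")

  # spearman variant runs
  expect_gt(interitem_variance_analysis(tr, method = "spearman")$r, 0.999)
})

test_that("similarity ranges shrink as compression grows", {
  obs <- observer_spec(dprime = 2, kappa = 5, period = 180,
                       compression = c("1" = 0, "2" = 0.3, "4" = 0.6,
                                       "8" = 0.8))
  profs <- lapply(c(1, 2, 4, 8), function(n) observer_profile(obs, 30, n))
  rng <- similarity_range_by_setsize(profs)
  expect_equal(rng$set_size, c(1, 2, 4, 8))
  expect_equal(rng$mean_range, 2 * (1 - c(0, 0.3, 0.6, 0.8)),
               tolerance = 1e-9)
  expect_true(all(diff(rng$mean_range) < 0))

  # constant profile: range zero
  const <- similarity_profile(rep(0.5, 360), condition = 1)
  expect_equal(similarity_range_by_setsize(list(const))$mean_range, 0)
})
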