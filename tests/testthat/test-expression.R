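test_that("deterministic response is a scaled Hill function", {
  p <- default_params
  expect_equal(deterministic_response(0.13, p), 0.5)          # midpoint
  expect_identical(deterministic_response(0, p), 0)           # no lactose
  expect_equal(deterministic_response(0.26, p), 16 / 17, tolerance = 1e-12)
  expect_equal(deterministic_response(0.13, p, copy_spec(c(0.5, 0.5))), 0.5)
  expect_equal(deterministic_response(0.13, p, copy_spec(c(1, 1))), 1)
})

test_that("zero noise makes the stochastic response exactly deterministic", {
  p <- default_params
  xs <- c(0.01, 0.13, 1, 10)
  for (cs in list(copy_spec(1), copy_spec(c(0.5, 0.5)))) {
    y <- stochastic_response(xs, p, cs, noise_params(0, 0), seed = 1)$y
    expect_identical(y, deterministic_response(xs, p, cs))
  }
})

test_that("with purely extrinsic noise a dosage-sharing duplicate is
           bit-identical to the singleton", {
  noise <- noise_params(eta_in = 0, eta_ex = 0.5)
  y1 <- stochastic_response(0.13, copies = copy_spec(1), noise = noise,
                            n = 500, seed = 99)$y
  y2 <- stochastic_response(0.13, copies = copy_spec(c(0.5, 0.5)),
                            noise = noise, n = 500, seed = 99)$y
  expect_identical(y1, y2)
})

test_that("stochastic response is bounded, monotone in dose at fixed draw,
           and symmetric around the midpoint under log-symmetric noise", {
  p <- default_params
  res <- stochastic_response(0.13, p, copy_spec(c(0.5, 0.5)),
                             noise_params(0.7, 0.4), n = 2000, seed = 3)
  expect_true(all(res$y >= 0 & res$y <= 1))
  # monotone in x for a frozen noise draw
  xs <- log_grid(1e-3, 10, 30)
  draw <- list(z0 = rep(1.3, 30), z = matrix(c(0.7, 1.6), 30, 2,
                                             byrow = TRUE))
  y <- dupsel:::expression_from_draw(xs, p, copy_spec(c(0.5, 0.5)), draw)
  expect_true(all(diff(y) > 0))
  # mean ~ 0.5 at the midpoint: y(u) + y(1/u) = 1 under symmetric log-noise
  ym <- stochastic_response(0.13, p, copy_spec(1), noise_params(0.5, 0),
                            n = 1e4, seed = 4)$y
  expect_equal(mean(ym), 0.5, tolerance = 0.02)
})

test_that("expression CV reproduces the reported noise magnitudes", {
  p <- default_params
  expect_identical(expression_cv(0.13, p, n_samples = 100, seed = 1), 0)
  cv_low <- expression_cv(0.13, p, noise = noise_params(0.1, 0.1),
                          n_samples = 1e5, seed = 2)
  cv_high <- expression_cv(0.13, p, noise = noise_params(0.5, 0.5),
                           n_samples = 1e5, seed = 3)
  expect_equal(cv_low, 0.26, tolerance = 0.02)
  expect_equal(cv_high, 0.72, tolerance = 0.02)
  expect_warning(cv0 <- expression_cv(0, p, n_samples = 100, seed = 4),
                 "undefined")
  expect_true(is.na(cv0))
})

test_that("duplication halves intrinsic expression variance; extrinsic noise
           dilutes the reduction", {
  p <- default_params
  # intrinsic only: exact halving (two iid halved responses)
  vr_in <- variance_reduction(0.13, p, noise_params(0.5, 0),
                              n_samples = 1e5, seed = 5)
  expect_equal(vr_in, 0.5, tolerance = 0.02)
  # mixed noise: partial reduction, in the reported band when extrinsic
  # noise moderately dominates
  vr_mix <- variance_reduction(0.13, p, noise_params(0.3, 0.4),
                               n_samples = 1e5, seed = 6)
  expect_gt(vr_mix, 0.15)
  expect_lt(vr_mix, 0.25)
  # equal moderate amplitudes: between the mixed band and the intrinsic bound
  vr_eq <- variance_reduction(0.13, p, noise_params(0.3, 0.3),
                              n_samples = 1e5, seed = 7)
  expect_gt(vr_eq, 0.15)
  expect_lt(vr_eq, 0.5)
})

test_that("median dose-response collapses to the deterministic curve without
           noise and stays at 0.5 at the midpoint with noise", {
  p <- default_params
  doses <- log_grid(0.013, 1.3, 15)
  flat <- median_dose_response(doses, p, n_samples = 200, seed = 8)
  expect_equal(flat$y, deterministic_response(doses, p), tolerance = 1e-12)
  noisy <- median_dose_response(0.13 * c(0.99, 1, 1.01), p,
                                noise = noise_params(0.5, 0.5),
                                n_samples = 4000, seed = 9)
  expect_equal(noisy$y[2], 0.5, tolerance = 0.03)
})

test_that("Hill fitting recovers the deterministic curve and the flattened
           duplicate response", {
  p <- default_params
  doses <- log_grid(p$x0 / 30, 30 * p$x0, 40)
  det <- data.frame(x = doses, y = deterministic_response(doses, p))
  fit <- hill_slope_at_x0(det, p)
  expect_equal(fit$n_eff, 4, tolerance = 1e-3)
  expect_equal(fit$slope, 1, tolerance = 1e-3)
  expect_equal(fit$midpoint, 0.13, tolerance = 1e-3)
  # duplicate under intrinsic noise: effective Hill ~3, midpoint slope ~0.75
  med <- median_dose_response(doses, p, copy_spec(c(0.5, 0.5)),
                              noise_params(0.5, 0), n_samples = 3000,
                              seed = 10)
  fit2 <- hill_slope_at_x0(med, p)
  expect_equal(fit2$n_eff, 3, tolerance = 0.15)
  expect_equal(fit2$slope, 0.75, tolerance = 0.07)
  # doubling the curve amplitude doubles the slope, not the Hill coefficient
  det2 <- det; det2$y <- 2 * det2$y
  fit3 <- hill_slope_at_x0(det2, p)
  expect_equal(fit3$slope, 2 * fit$slope, tolerance = 1e-3)
  expect_equal(fit3$n_eff, fit$n_eff, tolerance = 1e-3)
  expect_error(hill_slope_at_x0(det[15:20, ], p), "decade")
})

test_that("the wild-type regulation ranks among the closest to optimal", {
  dev <- curve_deviation_test(m = 1000, seed = 11)
  expect_lt(dev$p, 0.06)
  expect_gt(dev$p, 0)
  # degenerate candidate range: every curve ties the wild type
  dev0 <- curve_deviation_test(x0_range = c(0.13, 0.13), m = 100, seed = 12)
  expect_identical(dev0$p, 1)
  # the wild-type curve has zero distance to itself by construction
  p2 <- fitness_params()
  grid <- log_grid(0.001, 10, 50)
  expect_equal(sqrt(sum((dupsel:::hill_response(grid, p2) -
                           dupsel:::hill_response(grid, p2))^2)), 0)
})
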