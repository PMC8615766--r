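# Curve inversion: initial guess, noiseless round trip, scaling behavior
# and guard rails.

test_that("initializer lands within a factor of two of the true moment", {
  p <- ensemble_params(2e-6, 30000, 0.5, 0.25, 5)
  curve <- make_curve(p, coarse_drive(by = 10))
  drv <- attr(curve, "drive")
  init <- initialize_params(curve, drv)
  expect_gt(init$M_C, 30000 / 2)
  expect_lt(init$M_C, 30000 * 2)
  # amplitude-doubled curve doubles the magnetization guess only
  curve2 <- curve
  curve2$re <- 2 * curve2$re; curve2$im <- 2 * curve2$im
  init2 <- initialize_params(curve2, drv)
  expect_equal(init2$M_tilde, 2 * init$M_tilde, tolerance = 1e-6)
  expect_equal(init2$M_C, init$M_C)
  # flat curve is rejected
  flat <- curve
  flat$re <- rep(0, nrow(flat)); flat$im <- rep(0, nrow(flat))
  expect_error(initialize_params(flat, drv), "extremum")
})

test_that("noiseless solution-row curve is recovered within 1%", {
  truth <- solution_params()
  curve <- make_curve(truth, drive_conditions())
  fit <- suppressWarnings(fit_m2(curve, drive_conditions()))
  expect_true(fit$converged)
  expect_equal(fit$params$M_C, truth$M_C, tolerance = 0.01)
  expect_equal(fit$params$M_tilde, truth$M_tilde, tolerance = 0.01)
  # residual floor well under the peak amplitude
  expect_lt(fit$residual_rms, 1e-3 * max(abs(curve$re)))
  # tau_N is reported consistently with (M_C, alpha)
  expect_equal(fit$params$tau_N,
               neel_time(fit$params$M_C, fit$params$alpha), tolerance = 1e-9)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_true(all(td$std.error >= 0))
  g <- glance(fit)
  expect_identical(g$applicability, "PASS")
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("a rescaled curve rescales only the saturation magnetization", {
  truth <- solution_params()
  curve <- make_curve(truth, coarse_drive(by = 10))
  drv <- attr(curve, "drive")
  kappa <- 2.5
  curve2 <- curve
  curve2$re <- kappa * curve2$re; curve2$im <- kappa * curve2$im
  init <- ensemble_params(kappa * truth$M_tilde, truth$M_C, truth$sigma,
                          truth$alpha, truth$E_A)
  fit <- suppressWarnings(
    fit_m2(curve2, drv, init = init, multistart = 1,
           control = list(maxiter = 30, profile_EA = FALSE)))
  expect_equal(fit$params$M_tilde, kappa * truth$M_tilde, tolerance = 0.01)
  expect_equal(fit$params$M_C, truth$M_C, tolerance = 0.02)
})

test_that("FAIL applicability blocks fitting unless forced", {
  p <- solution_params()
  drv <- coarse_drive(by = 20)
  nm <- noise_model(sigma_abs = 1e-12,
                    hysteresis_offset = c("8" = 0.1, "0.25" = 0.1))
  s8 <- simulate_sweep(p, drv, 8, nm)
  s025 <- simulate_sweep(p, drv, 0.25, nm)
  curve <- preprocess_sweeps(s8[c("direct", "reverse")],
                             s025[c("direct", "reverse")])
  expect_identical(attr(curve, "applicability")$flag, "FAIL")
  expect_error(fit_m2(curve, drv), "inapplicable")
})
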