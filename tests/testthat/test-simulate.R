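# Synthetic sweep generator: determinism, noise statistics, hysteresis
# injection, and the phantom-study manifest.

test_that("zero-noise simulation equals the forward model on both branches", {
  p <- solution_params()
  drv <- coarse_drive(by = 50)
  sw <- simulate_sweep(p, drv, F_sc = 8, noise = noise_model(sigma_abs = 0))
  model <- ensemble_m2(p, drv)
  expect_equal(sw$direct$re, model$re)
  expect_equal(rev(sw$reverse$re), model$re)
  expect_identical(attr(sw$direct, "direction"), "direct")
  expect_true(all(diff(sw$reverse$H) < 0))
})

test_that("simulation is bitwise deterministic given the seed", {
  p <- solution_params()
  drv <- coarse_drive(by = 50)
  nm <- noise_model(sigma_abs = 1e-11, hysteresis_offset = 0.05, seed = 42)
  a <- simulate_sweep(p, drv, 8, nm)
  b <- simulate_sweep(p, drv, 8, nm)
  expect_identical(a$direct$re, b$direct$re)
  expect_identical(a$reverse$im, b$reverse$im)
  # different seed, different draw
  nm2 <- noise_model(sigma_abs = 1e-11, seed = 43)
  expect_false(identical(simulate_sweep(p, drv, 8, nm2)$direct$re,
                         a$direct$re))
})

test_that("noise statistics match the requested standard deviation", {
  p <- solution_params()
  drv <- drive_conditions(H_grid = seq(-300, 300, length.out = 301))
  sig <- 2e-11
  sw <- simulate_sweep(p, drv, 8, noise_model(sigma_abs = sig, seed = 7))
  model <- ensemble_m2(p, drv)
  resid <- c(sw$direct$re - model$re, sw$direct$im - model$im)
  expect_gt(length(resid), 200)
  expect_equal(sd(resid), sig, tolerance = 0.1)
})

test_that("injected hysteresis drives the applicability screen end to end", {
  p <- solution_params()
  drv <- coarse_drive(by = 20)
  both <- noise_model(sigma_abs = 1e-12,
                      hysteresis_offset = c("8" = 0.1, "0.25" = 0.1))
  s8 <- simulate_sweep(p, drv, 8, both)
  s025 <- simulate_sweep(p, drv, 0.25, both)
  expect_identical(
    superparamagnetic_check(s8[c("direct", "reverse")],
                            s025[c("direct", "reverse")])$flag, "FAIL")
  fast_only <- noise_model(sigma_abs = 1e-12,
                           hysteresis_offset = c("8" = 0.1, "0.25" = 0))
  s8b <- simulate_sweep(p, drv, 8, fast_only)
  s025b <- simulate_sweep(p, drv, 0.25, fast_only)
  expect_identical(
    superparamagnetic_check(s8b[c("direct", "reverse")],
                            s025b[c("direct", "reverse")])$flag, "PASS")
})

test_that("phantom manifest satisfies the count identities and spans the
           reference range", {
  st <- phantom_study(drive = coarse_drive(by = 60),
                      noise = noise_model(sigma_abs = 0))
  out <- withr::local_tempdir()
  res <- make_phantom_study(st, out)
  mf <- res$manifest
  # identities hold exactly by construction
  expect_equal(mf$N_P, count_centers(mf$M_tilde, mf$M_C))
  expect_equal(mf$N_MSC, count_mscs(mf$N_P))
  # organ cell densities span the reference rat 1 range
  organs <- mf[mf$organ != "solution", ]
  expect_equal(min(organs$N_MSC), 8.7e3, tolerance = 0.05)
  expect_equal(max(organs$N_MSC), 3.9e5, tolerance = 0.05)
  expect_identical(nrow(mf), 9L)   # 8 organs + solution
  # one file per (organ, F_sc, branch)
  expect_identical(length(res$files), 9L * 2L * 2L)
  expect_true(file.exists(file.path(out, "manifest.csv")))
})

test_that("empty organ list yields a solution-only manifest", {
  sol <- solution_params()
  st <- phantom_study(
    organs = tibble::tibble(organ = "solution", M_tilde = sol$M_tilde,
                            M_C = sol$M_C, sigma = sol$sigma,
                            alpha = sol$alpha, E_A = sol$E_A),
    drive = coarse_drive(by = 100), noise = noise_model(sigma_abs = 0))
  out <- withr::local_tempdir()
  res <- make_phantom_study(st, out)
  expect_identical(nrow(res$manifest), 1L)
  expect_identical(res$manifest$organ, "solution")
})
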