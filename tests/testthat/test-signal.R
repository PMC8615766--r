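# Preprocessing: branch averaging, antisymmetrization, hysteresis index and
# the applicability screen.

mk_branch <- function(H, re, im = rep(0, length(H)), direction = "direct",
                      F_sc = 8, drive = drive_conditions(), label = "t") {
  field_sweep_branch(H, re, im, direction, F_sc, drive, label)
}

test_that("average_branches handles equal, opposite and offset pairs", {
  H <- seq(-300, 300, by = 10)
  s <- sin(H / 100)
  d <- mk_branch(H, s)
  r <- mk_branch(rev(H), rev(s), direction = "reverse")
  avg <- average_branches(d, r)
  expect_equal(avg$re, s, tolerance = 1e-12)

  r_neg <- mk_branch(rev(H), rev(-s), direction = "reverse")
  expect_equal(average_branches(d, r_neg)$re, rep(0, length(H)),
               tolerance = 1e-12)

  # symmetric hysteretic pair +delta / -delta averages to the base curve
  delta <- 0.05
  d2 <- mk_branch(H, s + delta)
  r2 <- mk_branch(rev(H), rev(s - delta), direction = "reverse")
  expect_equal(average_branches(d2, r2)$re, s, tolerance = 1e-12)
})

test_that("average_branches rejects inconsistent acquisitions", {
  H <- seq(-300, 300, by = 50)
  d <- mk_branch(H, sin(H / 100))
  r_fsc <- mk_branch(rev(H), rev(sin(H / 100)), direction = "reverse",
                     F_sc = 0.25)
  expect_error(average_branches(d, r_fsc), "scan frequencies")
  r_drv <- mk_branch(rev(H), rev(sin(H / 100)), direction = "reverse",
                     drive = drive_conditions(h = 10))
  expect_error(average_branches(d, r_drv), "drive")
  r_short <- mk_branch(seq(200, 300, by = 50), rep(0, 3),
                       direction = "reverse")
  expect_error(average_branches(d, r_short), "overlap")
})

test_that("antisymmetrize extracts the odd part", {
  H <- seq(-300, 300, by = 10)
  # even input vanishes
  even <- antisymmetrize(mk_branch(H, H^2))
  expect_equal(even$re, rep(0, nrow(even)), tolerance = 1e-12)
  # odd input is unchanged on the nonnegative grid
  odd <- antisymmetrize(mk_branch(H, H^3, im = 3 * H))
  expect_equal(odd$re, odd$H^3, tolerance = 1e-9)
  expect_equal(odd$im, 3 * odd$H, tolerance = 1e-12)
  # mixed input: s(H) = H^2 + 3H -> odd part 3H
  mixed <- antisymmetrize(mk_branch(H, H^2 + 3 * H))
  expect_equal(mixed$re, 3 * mixed$H, tolerance = 1e-9)
  # curve passes through zero exactly
  expect_identical(mixed$re[mixed$H == 0], 0)
  # idempotence: antisymmetrizing an odd curve again changes nothing
  H2 <- c(-rev(odd$H[-1]), odd$H)
  again <- antisymmetrize(mk_branch(H2, H2^3, im = 3 * H2))
  expect_equal(again$re, odd$re, tolerance = 1e-9)
  expect_error(antisymmetrize(mk_branch(seq(0, 300, 10), seq(0, 300, 10))),
               "both signs")
})

test_that("hysteresis index has the expected closed-form values", {
  H <- seq(-300, 300, by = 10)
  s <- sin(H / 80)
  d <- mk_branch(H, s)
  r_same <- mk_branch(rev(H), rev(s), direction = "reverse")
  expect_equal(hysteresis_index(d, r_same), 0)

  # constant complex shift of half the peak-to-peak amplitude -> index 0.5;
  # note the mean curve's amplitude is unchanged by a constant shift
  ptp <- diff(range(s))
  r_shift <- mk_branch(rev(H), rev(s + ptp / 2), direction = "reverse")
  expect_equal(hysteresis_index(d, r_shift), 0.5, tolerance = 1e-10)

  # invariant under a common rescaling of both branches
  d10 <- mk_branch(H, 10 * s)
  r10 <- mk_branch(rev(H), rev(10 * (s + ptp / 2)), direction = "reverse")
  expect_equal(hysteresis_index(d10, r10),
               hysteresis_index(d, r_shift), tolerance = 1e-12)

  flat_d <- mk_branch(H, rep(1, length(H)))
  flat_r <- mk_branch(rev(H), rep(1, length(H)), direction = "reverse")
  expect_error(hysteresis_index(flat_d, flat_r), "flat")
})

test_that("applicability screen classifies the three hysteresis regimes", {
  pair <- function(off) {
    H <- seq(-300, 300, by = 10)
    s <- sin(H / 80)
    list(direct = mk_branch(H, s + off),
         reverse = mk_branch(rev(H), rev(s - off), direction = "reverse"))
  }
  # clean superparamagnetic signal
  expect_identical(superparamagnetic_check(pair(0), pair(0))$flag, "PASS")
  # scan-rate independent hysteresis: the multi-domain failure mode
  chk_fail <- superparamagnetic_check(pair(0.1), pair(0.1))
  expect_identical(chk_fail$flag, "FAIL")
  # hysteresis only at the fast scan: still superparamagnetic
  chk_pass <- superparamagnetic_check(pair(0.1), pair(0))
  expect_identical(chk_pass$flag, "PASS")
  expect_true(any(grepl("decreases", chk_pass$notes)))
  # deterministic given inputs and thresholds
  expect_identical(superparamagnetic_check(pair(0.1), pair(0.1))$flag,
                   chk_fail$flag)
})

test_that("averaging commutes with antisymmetrization on model data", {
  p <- solution_params()
  drv <- coarse_drive(by = 30)
  sw <- simulate_sweep(p, drv, F_sc = 8, noise = noise_model(sigma_abs = 0))
  a_then_s <- antisymmetrize(average_branches(sw$direct, sw$reverse))
  s_direct <- antisymmetrize(sw$direct)
  s_reverse <- antisymmetrize(sw$reverse)
  expect_equal(a_then_s$re, (s_direct$re + s_reverse$re) / 2,
               tolerance = 1e-12)
  # noiseless model branches carry no hysteresis
  expect_lt(hysteresis_index(sw$direct, sw$reverse), 1e-10)
})
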