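# Count conversion, amplitude scaling, organ ranking and report layout.

test_that("count_centers reproduces the printed center counts", {
  expect_equal(count_centers(3.633e-6, 31580), 1.24e10, tolerance = 0.01)
  expect_equal(count_centers(6.495e-6, 26400), 2.65e10, tolerance = 0.01)
  expect_equal(count_centers(0, 31580), 0)
  expect_error(count_centers(1e-6, 0), "M_C")
})

test_that("count_mscs divides by the aggregates-per-cell calibration", {
  expect_equal(count_mscs(1.24e10), 1.5e5, tolerance = 0.005)
  expect_equal(count_mscs(1.01e11), 1.2e6, tolerance = 0.02)
  expect_equal(count_mscs(0), 0)
})

test_that("count identities hold for every processed reference row", {
  rows <- processed_reference_rows()
  np <- count_centers(rows$M_tilde, rows$M_C)
  expect_true(all(abs(np / rows$N_P - 1) < 0.01))
  nm <- count_mscs(np)
  expect_equal(signif(nm, 2), signif(rows$N_MSC, 2), tolerance = 1e-9)
})

test_that("amplitude scaling is linear and preserves the reference moment", {
  ref <- organ_record("brain", "rat1", 4.303e-7, 39400, status = "fitted")
  same <- amplitude_scaled_estimate(ref, amp_ref = 1, amp_target = 1,
                                    organ = "pancreas")
  expect_equal(same$M_tilde, ref$M_tilde)
  expect_equal(same$N_MSC, ref$N_MSC)
  expect_identical(same$status, "amplitude-scaled")

  dbl <- amplitude_scaled_estimate(ref, 1, 2, organ = "pancreas")
  expect_equal(dbl$M_tilde, 2 * ref$M_tilde)
  expect_equal(dbl$N_P, 2 * ref$N_P)
  expect_error(amplitude_scaled_estimate(ref, 0, 1, "x"), "amplitude")
  scaled_ref <- dbl
  expect_error(amplitude_scaled_estimate(scaled_ref, 1, 1, "x"), "fitted")
})

test_that("amplitude scaling recovers a known magnetization ratio", {
  # generate two curves from the forward model with M_tilde ratio 0.37 and
  # recover the ratio from their peak amplitudes
  drv <- coarse_drive(by = 20)
  p_ref <- solution_params()
  p_tgt <- ensemble_params(0.37 * p_ref$M_tilde, p_ref$M_C, p_ref$sigma,
                           p_ref$alpha, p_ref$E_A)
  m_ref <- ensemble_m2(p_ref, drv)
  m_tgt <- ensemble_m2(p_tgt, drv)
  ref <- organ_record("liver", "rat1", p_ref$M_tilde, p_ref$M_C,
                      status = "fitted")
  est <- amplitude_scaled_estimate(ref, max(abs(m_ref$re)),
                                   max(abs(m_tgt$re)), organ = "spleen")
  expect_equal(est$M_tilde / ref$M_tilde, 0.37, tolerance = 1e-6)
})

test_that("organ ranking reproduces both printed orderings", {
  ref <- reference_biodistribution()
  r1 <- rank_organs(ref[ref$subject == "rat1", ])
  expect_identical(r1$organ, c("pancreas", "brain", "skin", "spleen",
                               "lungs", "tumor", "muscle", "liver"))
  r2 <- rank_organs(ref[ref$subject == "rat2", ])
  expect_identical(r2$organ, c("brain", "pancreas", "muscle", "spleen",
                               "tumor", "skin", "liver", "lungs"))
  # invariant under a common rescaling of all counts
  scaled <- ref[ref$subject == "rat1", ]
  scaled$N_MSC <- scaled$N_MSC * 3.7
  expect_identical(rank_organs(scaled)$organ, r1$organ)
  expect_error(rank_organs(ref), "one subject")
  expect_error(rank_organs(ref[1, ]), "two")
})

test_that("summary table formats approximate and missing entries", {
  recs <- dplyr::bind_rows(
    organ_record("tumor", "rat1", 6.495e-6, 26400, status = "fitted"),
    amplitude_scaled_estimate(
      organ_record("brain", "rat1", 4.303e-7, 39400, status = "fitted"),
      1, 0.6, organ = "pancreas"))
  out <- summary_table(recs)
  expect_named(out, c("table", "chart_data"))
  tab <- out$table
  expect_identical(nrow(tab), 2L)
  expect_false(any(grepl("^~", tab$M_tilde[tab$status == "fitted"])))
  expect_true(all(grepl("^~", tab$M_tilde[tab$status == "amplitude-scaled"])))
  expect_identical(tab$sigma[tab$status == "amplitude-scaled"], "-")
  expect_identical(nrow(out$chart_data), 2L)
  p <- plot_biodistribution(recs)
  expect_s3_class(p, "ggplot")
})
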