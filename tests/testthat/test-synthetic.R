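test_that("dose field hits the peak at centre and decays outside the FOV", {
  ph <- build_phantom(
    list(phantom_layer(1, thickness_mm = 50)),
    list(dosimeter_record(1, 1, "centre", "skin", depth_mm = 0)))
  prot <- protocol_spec("toy", "CBCT", 110, 10, fov_length_mm = 50)
  params <- dose_field_params(peak_dose = 8)
  expect_equal(unname(generate_dose_field(prot, ph, params)), 8)

  # zero attenuation and full coverage give a uniform field
  ph20 <- default_ankle_phantom()
  flat <- dose_field_params(peak_dose = 5, depth_mu = 0)
  wide <- protocol_spec("wide", "CBCT", 110, 10, fov_length_mm = 150)
  f <- generate_dose_field(wide, ph20, flat)
  expect_true(all(f == 5))

  # a FOV missing the phantom leaves only scatter, with a warning
  expect_warning(
    sc <- generate_dose_field(wide, ph20, flat, fov_offset_mm = 1000),
    "scatter")
  expect_true(all(sc > 0 & sc < 5))
})

test_that("default field reproduces the ~40x in-field/out-of-field spread", {
  ph <- default_ankle_phantom()
  prot <- default_protocols()$cbct_hires_12x8
  f <- generate_dose_field(prot, ph, dose_field_params())
  expect_true(all(f > 0))
  ratio <- max(f) / min(f)
  expect_gt(ratio, 25)
  expect_lt(ratio, 55)
  # proximal (out-of-field) layers see far less dose than distal ones
  pl <- default_ankle_phantom()$placements
  expect_lt(max(f[as.character(pl$dosimeter_no[pl$layer == 23])]),
            min(f[as.character(pl$dosimeter_no[pl$layer == 28])]))
})

test_that("reading noise is seeded, dose-dependent and truncation is logged", {
  truth <- c(`1` = 0.25, `2` = 4, `3` = 10.4)
  nm <- noise_model()
  expect_gt(sigma_rel(nm, 0.25), sigma_rel(nm, 4))
  expect_equal(sigma_rel(nm, 0.25), 33)
  r1 <- sample_readings(truth, nm, 6, seed = 42)
  r2 <- sample_readings(truth, nm, 6, seed = 42)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 18)
  expect_false(identical(r1$dose_mGy,
                         sample_readings(truth, nm, 6, seed = 43)$dose_mGy))
  # zero noise returns the truth exactly
  r0 <- sample_readings(truth, noise_model(0, 0), 3, seed = 1)
  expect_equal(r0$dose_mGy, rep(unname(truth), each = 3))
  expect_equal(attr(r0, "n_truncated"), 0)
  # absurd noise must truncate some draws and say so
  rt <- sample_readings(truth, noise_model(300, 0), 50, seed = 1)
  expect_gt(attr(rt, "n_truncated"), 0)
  expect_true(all(rt$dose_mGy >= 0))
  expect_error(sample_readings(truth, nm, 6), "seed")
})

test_that("empirical spread of six-exposure readings is centred near the model value", {
  # Monte-Carlo: at 0.25 mGy the model says 33% relative SD; the sample SD of
  # n=6 is slightly biased low (c4 ~ 0.95), so the mean empirical rel_sd
  # should sit a little under 33
  nm <- noise_model()
  rel_sds <- vapply(1:1000, function(s) {
    r <- sample_readings(c(`1` = 0.25), nm, 6, seed = s)
    mean_dose(r$dose_mGy)$rel_sd
  }, numeric(1))
  expect_gt(mean(rel_sds), 28)
  expect_lt(mean(rel_sds), 36)
})

test_that("ground truth equals the engine on noiseless doses and is linear", {
  ph <- default_ankle_phantom()
  fr <- default_ankle_fractions()
  w <- default_icrp_weights()
  est <- ankle_study_doses()
  truth <- stats::setNames(est$mean_dose, est$dosimeter_no)
  gt <- ground_truth_effective_dose(truth, ph, fr, w)
  expect_equal(gt$E_uSv, compute_effective_dose(est, ph, fr, w)$E_uSv)
  expect_equal(gt$E_uSv, 14.585, tolerance = 1e-4)
  expect_equal(ground_truth_effective_dose(2 * truth, ph, fr, w)$E_uSv,
               2 * gt$E_uSv)
  expect_equal(ground_truth_effective_dose(0 * truth, ph, fr, w)$E_uSv, 0)
})

test_that("fixture bundles are complete, reproducible and recoverable", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  fx <- make_fixture(7, dir = d1)
  fx2 <- make_fixture(7, dir = d2)
  expect_equal(length(unique(fx$readings$dosimeter_no)), 20)
  expect_equal(nrow(fx$readings), 120)
  expect_identical(fx$readings, fx2$readings)
  for (f in names(fx$files)) {
    expect_identical(readLines(fx$files[[f]]), readLines(fx2$files[[f]]))
  }
  # estimate from the bundle recovers E_true within 4 analytic SEs
  est <- estimates_from_readings(fx$readings)
  E_hat <- compute_effective_dose(est, fx$phantom, fx$fractions,
                                  fx$weights)$E_uSv
  se <- effective_dose_se(fx$true_doses, fx$phantom, fx$fractions,
                          fx$weights)
  expect_lt(abs(E_hat - fx$truth$E_uSv), 4 * se)
  # the written bundle re-runs end to end from files alone
  res <- run_study(study_config(
    readings = fx$files[["readings"]],
    phantom = fx$files[["phantom"]],
    fractions = fx$files[["fractions"]],
    weights = fx$files[["weights"]]))
  expect_equal(res$effective_dose$E_uSv, E_hat)
})
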