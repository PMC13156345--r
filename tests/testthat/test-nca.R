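test_that("cmax ties break to the earliest time", {
  p <- conc_profile(c(1, 2, 3), c(10, 10, 5))
  expect_equal(unname(cmax_tmax(p)), c(10, 1))
  p1 <- conc_profile(0.5, 23)
  expect_equal(unname(cmax_tmax(p1)), c(23, 0.5))
  pc <- conc_profile(c(1, 2), c(NA, NA), censored = c(TRUE, TRUE))
  expect_true(all(is.na(cmax_tmax(pc))))
})

test_that("trapezoid rules give their closed-form areas", {
  # rising triangle, linear rule
  tri <- conc_profile(1, 10)  # with the implicit (0, 0) anchor
  expect_equal(auc_interval(tri, 0, 1), 5)
  # declining pair, logarithmic rule: (10 - 5) / ln 2
  dec <- conc_profile(c(1, 2), c(10, 5))
  expect_equal(auc_interval(dec, 1, 2), 5 / log(2))
  # pure-linear option on the same pair
  expect_equal(auc_interval(dec, 1, 2, method = "linear"), 7.5)
})

test_that("dense-grid AUC matches the analytic monoexponential integral", {
  p <- mono_profile(seq(0, 12, by = 0.01))
  analytic <- 100 / 0.2 * (1 - exp(-0.2 * 12))
  expect_lt(abs(auc_interval(p, 0, 12) - analytic) / analytic, 0.001)
})

test_that("AUC is additive over abutting windows and interpolates endpoints", {
  p <- conc_profile(clinical_grid, c(5, 12, 20, 18, 15, 11, 7, 4, 2.5, 1.5))
  a04 <- auc_interval(p, 0, 4)
  a412 <- auc_interval(p, 4, 12)
  a012 <- auc_interval(p, 0, 12)
  expect_equal(a04 + a412, a012, tolerance = 1e-9)
  # off-grid window ends are interpolated under the same rule
  a05 <- auc_interval(p, 0, 5)
  a512 <- auc_interval(p, 5, 12)
  expect_equal(a05 + a512, a012, tolerance = 1e-9)
})

test_that("appending a later point never decreases AUC to tlast", {
  p <- conc_profile(c(1, 2, 4), c(10, 6, 3))
  p_ext <- conc_profile(c(1, 2, 4, 6), c(10, 6, 3, 1))
  expect_gte(auc_interval(p_ext, 0, 6), auc_interval(p, 0, 4))
})

test_that("censored interior points are bridged, not zeroed", {
  full <- conc_profile(c(1, 2, 3), c(10, exp(mean(log(c(10, 5)))), 5))
  holed <- conc_profile(c(1, 2, 3), c(10, NA, 5),
                        censored = c(FALSE, TRUE, FALSE))
  # bridging the censored point log-interpolates straight across
  expect_equal(auc_interval(holed, 1, 3), 2 * 5 / log(2))
  expect_lt(abs(auc_interval(full, 1, 3) - auc_interval(holed, 1, 3)),
            0.03)
})

test_that("terminal slope recovers an exact monoexponential tail", {
  p <- mono_profile(c(1, 4, 6, 8, 10, 12))
  ts <- terminal_slope(p)
  expect_equal(unname(ts["lambda_z"]), 0.2, tolerance = 1e-10)
  expect_equal(unname(ts["t_half_h"]), log(2) / 0.2, tolerance = 1e-9)
  expect_gte(unname(ts["lz_n_points"]), 3)
})

test_that("profiles with no terminal decline report missing endpoints", {
  rising <- conc_profile(c(1, 2, 4, 8), c(1, 3, 6, 10))
  expect_true(all(is.na(terminal_slope(rising))))
  r <- nca(rising)
  expect_true(is.na(r$t_half_h) && is.na(r$auc_inf) && is.na(r$cl_f_Lh))
})

test_that("lambda_z is scale invariant and AUC scales linearly", {
  noisy_tail <- conc_profile(c(2, 4, 6, 8, 10, 12),
                             c(50, 28, 16, 9.5, 5.2, 3.1))
  base <- terminal_slope(noisy_tail)
  scaled <- conc_profile(c(2, 4, 6, 8, 10, 12),
                         10 * c(50, 28, 16, 9.5, 5.2, 3.1))
  expect_equal(unname(terminal_slope(scaled)["lambda_z"]),
               unname(base["lambda_z"]))
  expect_equal(auc_interval(scaled, 2, 12),
               10 * auc_interval(noisy_tail, 2, 12))
})

test_that("grid refinement converges toward the analytic integral", {
  analytic <- 100 / 0.2 * (1 - exp(-0.2 * 12))
  err <- sapply(c(2, 1, 0.5, 0.25), function(h) {
    p <- mono_profile(seq(h, 12, by = h))
    abs(auc_interval(p, 0, 12) - analytic)
  })
  expect_true(all(diff(err) < 0))
})

test_that("nca assembles extrapolation, clearance and diagnostics", {
  p <- mono_profile(c(0.5, 1, 2, 4, 6, 8, 10, 12), dose_nmol = 8763,
                    analyte = "letrozole")
  r <- nca(p)
  expect_equal(r$auc_inf, r$auc_0_tlast +
                 100 * exp(-0.2 * 12) / r$lambda_z, tolerance = 1e-6)
  expect_equal(r$cl_f_Lh, 8763 / r$auc_inf)
  expect_false(r$extrapolation_flag)
  # dose zero: clearance zero and flagged
  p0 <- mono_profile(c(1, 2, 4, 6, 8), dose_nmol = 0)
  r0 <- nca(p0)
  expect_equal(r0$cl_f_Lh, 0)
  expect_true(r0$invalid_dose)
})

test_that("high extrapolated fraction raises the reliability flag", {
  # truncate sampling well before one half-life has passed
  p <- mono_profile(c(0.25, 0.5, 1, 1.5, 2), k = 0.1, dose_nmol = 100)
  r <- nca(p)
  expect_gt(r$extrapolated_fraction, 0.2)
  expect_true(r$extrapolation_flag)
})
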