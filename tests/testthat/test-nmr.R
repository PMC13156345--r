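test_that("fixed-time ratios are plain concentration ratios", {
  cot <- conc_profile(c(4, 6, 8), c(64, 60, 45), analyte = "cotinine")
  ohc <- conc_profile(c(4, 6, 8), c(9.6, 12, 10.8))
  out <- nmr_at_times(cot, ohc)
  expect_equal(out$nmr, c(0.15, 0.2, 0.24))
})

test_that("a censored metabolite removes the point, never infinity", {
  cot <- conc_profile(c(4, 6, 8), c(64, 60, 45))
  ohc <- conc_profile(c(4, 6, 8), c(9.6, NA, 10.8),
                      censored = c(FALSE, TRUE, FALSE))
  out <- nmr_at_times(cot, ohc)
  expect_true(is.na(out$nmr[2]))
  expect_equal(out$nmr[c(1, 3)], c(0.15, 0.24))
  # zero cotinine excluded rather than dividing
  cot0 <- conc_profile(c(4, 6, 8), c(64, 0, 45))
  out0 <- nmr_at_times(cot0, ohc)
  expect_true(is.na(out0$nmr[2]))
})

test_that("the ratio is invariant to a common scale factor", {
  prof <- nicotine_metabolite_profiles()
  scaled <- list(
    cot = conc_profile(prof$cot$times_h, 3.7 * prof$cot$conc_nM),
    ohc = conc_profile(prof$ohc$times_h, 3.7 * prof$ohc$conc_nM))
  f1 <- fit_nmr_slope(prof$cot, prof$ohc)
  f2 <- fit_nmr_slope(scaled$cot, scaled$ohc)
  expect_equal(coef(f1), coef(f2))
  expect_equal(f1$pauc_ratio_3_8, f2$pauc_ratio_3_8)
  expect_equal(nmr_at_times(prof$cot, prof$ohc)$nmr,
               nmr_at_times(scaled$cot, scaled$ohc)$nmr)
})

test_that("partial-AUC ratio handles identity and proportional profiles", {
  cot <- conc_profile(clinical_grid,
                      c(20, 35, 45, 52, 60, 64, 57, 45, 34, 24))
  expect_equal(partial_auc_ratio(cot, cot), 1)
  ohc <- conc_profile(clinical_grid, 0.18 * cot$conc_nM)
  expect_equal(partial_auc_ratio(cot, ohc), 0.18, tolerance = 1e-9)
})

test_that("noise-free defaults give a partial-AUC ratio near the clinical 0.18", {
  prof <- nicotine_metabolite_profiles()
  pr <- partial_auc_ratio(prof$cot, prof$ohc)
  expect_lt(abs(pr - 0.18) / 0.18, 0.30)
  # the alternative time-averaged-ratio convention lands close by
  alt <- partial_auc_ratio(prof$cot, prof$ohc,
                           convention = "auc_of_ratio")
  expect_lt(abs(alt - pr) / pr, 0.25)
})

test_that("slope fits recover an exactly linear ratio", {
  t <- clinical_grid
  # slow metabolite decline keeps the downstream peak late so the
  # linear window [tmax_cot, tmax_ohc] holds enough points
  cot <- conc_profile(t, c(20, 35, 45, 52, 60, 64, 60, 55, 48, 40))
  ohc <- conc_profile(t, (0.02 * t + 0.05) * cot$conc_nM)
  fit <- fit_nmr_slope(cot, ohc)
  expect_equal(fit$slope_all, 0.02, tolerance = 1e-10)
  expect_equal(fit$slope_linear, 0.02, tolerance = 1e-10)
  # constant ratio: slope zero
  flat <- conc_profile(t, 0.15 * cot$conc_nM)
  expect_equal(fit_nmr_slope(cot, flat)$slope_all, 0,
               tolerance = 1e-12)
})

test_that("the linear window spans the two metabolite peaks", {
  prof <- nicotine_metabolite_profiles()
  fit <- fit_nmr_slope(prof$cot, prof$ohc)
  expect_equal(unname(fit$window),
               c(unname(cmax_tmax(prof$cot)["tmax_h"]),
                 unname(cmax_tmax(prof$ohc)["tmax_h"])))
  expect_gte(fit$n_points_linear, 3)
  expect_true(is.finite(fit$slope_linear))
})

test_that("fewer than three points leaves slopes missing", {
  cot <- conc_profile(c(4, 6), c(64, 60))
  ohc <- conc_profile(c(4, 6), c(9.6, 12))
  fit <- fit_nmr_slope(cot, ohc)
  expect_true(is.na(fit$slope_all) && is.na(fit$slope_linear))
})

test_that("slope scales with activity on the downstream CYP2A6 step", {
  base <- nicotine_metabolite_profiles(1)
  s1 <- fit_nmr_slope(base$cot, base$ohc)$slope_linear
  for (phi in c(0.5, 0.8)) {
    prof <- nicotine_metabolite_profiles(phi, steps = "m2_formation")
    s <- fit_nmr_slope(prof$cot, prof$ohc)$slope_linear
    expect_lt(abs(s / s1 - phi) / phi, 0.15)
  }
  # monotone in phi
  s5 <- fit_nmr_slope(nicotine_metabolite_profiles(0.5,
          steps = "m2_formation")$cot,
        nicotine_metabolite_profiles(0.5, steps = "m2_formation")$ohc)
  expect_lt(s5$slope_linear, s1)
})

test_that("pattern classification follows the slope ratio", {
  expect_equal(classify_pattern(0.022, 0.022), "parallel")
  expect_equal(classify_pattern(0.024, 0.015), "reduced_slope")
  expect_equal(classify_pattern(0.02, 0.03), "increased_slope")
  expect_true(is.na(classify_pattern(NA_real_, 0.02)))
})

test_that("simulated inhibition narratives classify as expected", {
  base <- nicotine_metabolite_profiles(1)
  fit_base <- fit_nmr_slope(base$cot, base$ohc)
  p <- nicotine_params()
  sim_with <- function(act) {
    prof <- simulate_profile(p, act, clinical_grid)
    fit_nmr_slope(
      conc_profile(prof$time_h, prof$cotinine),
      conc_profile(prof$time_h, prof$`3-hydroxycotinine`))
  }
  # inhibition accruing over the day: slope drops
  fit_pro <- sim_with(cyp2a6_activity(0.4, "progressive",
                                      k_change = 0.6))
  expect_equal(classify_pattern(fit_base, fit_pro), "reduced_slope")
  # inhibitor cleared quickly: activity back near 1, slopes parallel
  fit_rec <- sim_with(cyp2a6_activity(0.5, "recovering", k_change = 3))
  expect_equal(classify_pattern(fit_base, fit_rec), "parallel")
})
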