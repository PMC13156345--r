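test_that("constant full activity reproduces the Bateman solution", {
  p <- nicotine_params()
  prof <- simulate_profile(p, cyp2a6_activity(1), clinical_grid)
  direct <- bateman_chain(
    c(p$ka, p$cl_f / p$v_f, p$k_m1, p$k_m2), p$dose_nmol, clinical_grid,
    transfer = c(p$ka, p$f_m1 * p$cl_f / p$v_f, p$f_m2 * p$k_m1))
  expect_equal(prof$nicotine, unname(direct[, 2] / p$v_f))
  expect_equal(prof$cotinine,
               unname(direct[, 3] / (p$vol_ratio_m1 * p$v_f)))
})

test_that("a complete CYP2A6 block suppresses the downstream metabolite", {
  p <- nicotine_params()
  prof <- simulate_profile(p, cyp2a6_activity(0), clinical_grid,
                           steps = "m2_formation")
  expect_true(all(prof$`3-hydroxycotinine` == 0))
  expect_true(all(prof$cotinine > 0))  # formation step untouched
})

test_that("time-varying integration matches the closed form when flat", {
  p <- nicotine_params()
  flat <- cyp2a6_activity(0.7, mode = "recovering", k_change = 1e-9)
  const <- cyp2a6_activity(0.7)
  a <- simulate_profile(p, flat, c(1, 4, 12))
  b <- simulate_profile(p, const, c(1, 4, 12))
  expect_equal(a$nicotine, b$nicotine, tolerance = 1e-7)
  expect_equal(a$`3-hydroxycotinine`, b$`3-hydroxycotinine`,
               tolerance = 1e-7)
})

test_that("activity modes move in the documented directions", {
  act_rec <- cyp2a6_activity(0.4, "recovering", k_change = 0.5)
  act_pro <- cyp2a6_activity(0.4, "progressive", k_change = 0.5)
  t <- c(0, 2, 8, 24)
  expect_equal(activity_value(act_rec, 0), 0.4)
  expect_true(all(diff(activity_value(act_rec, t)) > 0))
  expect_equal(activity_value(act_pro, 0), 1)
  expect_true(all(diff(activity_value(act_pro, t)) < 0))
  expect_equal(activity_value(cyp2a6_activity(0.4), t), rep(0.4, 4))
})

test_that("noise-free nicotine defaults reproduce the clinical endpoints", {
  p <- nicotine_params()
  prof <- simulate_profile(p, times = clinical_grid)
  cp <- conc_profile(prof$time_h, prof$nicotine, analyte = "nicotine",
                     dose_nmol = p$dose_nmol)
  r <- nca(cp, auc_windows = list(c(0, 4)))
  expect_lt(abs(r$cmax_nM - 23) / 23, 0.25)
  expect_true(r$tmax_h >= 0.5 && r$tmax_h <= 1.5)
  expect_lt(abs(r$t_half_h - 3.4) / 3.4, 0.15)
  expect_lt(abs(r$cl_f_Lh - 111) / 111, 0.15)
  # closed-form AUC0-inf = dose / CL for linear kinetics (fine grid so
  # that trapezoid discretisation does not obscure the identity)
  fine <- simulate_profile(p, times = seq(0.05, 24, by = 0.05))
  rf <- nca(conc_profile(fine$time_h, fine$nicotine,
                         analyte = "nicotine", dose_nmol = p$dose_nmol))
  expect_lt(abs(rf$auc_inf - p$dose_nmol / p$cl_f) /
              (p$dose_nmol / p$cl_f), 0.01)
})

test_that("LOQ censoring follows the strict-below rule", {
  out <- apply_loq(c(0.5, 7.4, 8), 7.4)
  expect_equal(out$censored, c(TRUE, FALSE, FALSE))
  expect_true(is.na(out$conc_nM[1]))
  expect_equal(out$conc_nM[2:3], c(7.4, 8))
  expect_error(apply_loq(-1, 7.4), "negative")
  # default nicotine LOQ from the 1.2 ng/mL calibration limit
  expect_equal(unname(nicotine_loq_nM()["nicotine"]), 1.2e3 / 162.23)
  expect_equal(unname(nicotine_loq_nM()["nicotine"]), 7.40,
               tolerance = 1e-3)
})

test_that("no-noise, no-effect crossover gives unit AUC ratios", {
  d <- simulation_design(n_subjects = 4, intra_cv = 0,
                         prop_error_cv = 0, loq_nM = 0, seed = 3)
  ds <- simulate_crossover_study(d, nicotine_params())
  tr <- ds$truth
  for (s in unique(tr$subject_id)) {
    cl <- tr$cl_f[tr$subject_id == s]
    expect_equal(cl[1], cl[2])
  }
  wide <- reshape(ds$records[ds$records$analyte == "nicotine", ],
                  direction = "wide",
                  idvar = c("subject_id", "analyte", "time_h"),
                  timevar = "period",
                  v.names = c("conc_nM", "censored"))
  expect_equal(wide$conc_nM.baseline, wide$conc_nM.exposure)
})

test_that("reduced CYP2A6 activity lowers nicotine clearance in every subject", {
  d <- noise_free_design(n_subjects = 6, phi0 = 0.5, seed = 5)
  ds <- simulate_crossover_study(d, nicotine_params())
  tab <- nca_table(ds, dose_nmol = c(nicotine = nicotine_params()$dose_nmol))
  nic <- tab[tab$analyte == "nicotine", ]
  ratio <- nic$cl_f_Lh[nic$period == "exposure"] /
    nic$cl_f_Lh[nic$period == "baseline"]
  expect_true(all(ratio < 1))
})

test_that("identical seed and design give a bit-identical dataset", {
  d <- simulation_design(n_subjects = 3, seed = 99,
                         loq_nM = nicotine_loq_nM())
  a <- simulate_crossover_study(d, nicotine_params())
  b <- simulate_crossover_study(d, nicotine_params())
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  d2 <- simulation_design(n_subjects = 3, seed = 100,
                          loq_nM = nicotine_loq_nM())
  expect_false(identical(
    simulate_crossover_study(d2, nicotine_params())$records, a$records))
})

test_that("intra-subject CV propagates to the AUC log-ratio as sqrt(2) sigma", {
  # oracle: the log of a ratio of two independent log-normals has
  # sd sqrt(2) * sigma with sigma = sqrt(log(1 + cv^2))
  d <- simulation_design(n_subjects = 200, intra_cv = 0.26,
                         prop_error_cv = 0, loq_nM = 0, seed = 21)
  ds <- simulate_crossover_study(d, nicotine_params())
  tr <- ds$truth
  # AUC0-inf = dose / CL exactly in the linear cascade
  auc <- nicotine_params()$dose_nmol / tr$cl_f
  lr <- log(auc[tr$period == "exposure"]) -
    log(auc[tr$period == "baseline"])
  expected_sd <- sqrt(2) * sqrt(log(1 + 0.26^2))
  expect_lt(abs(sd(lr) - expected_sd) / expected_sd, 0.15)
})

test_that("simulated letrozole recovers its terminal half-life", {
  p <- letrozole_params()
  prof <- simulate_profile(p, times = letrozole_times())
  cp <- conc_profile(prof$time_h, prof$letrozole, analyte = "letrozole",
                     dose_nmol = p$dose_nmol)
  r <- nca(cp)
  expect_lt(abs(r$t_half_h - 46) / 46, 0.10)
  expect_lt(abs(r$cl_f_Lh - 2.16) / 2.16, 0.05)
})

test_that("design validation catches bad inputs", {
  expect_error(simulation_design(n_subjects = 1), "at least 2")
  expect_error(simulation_design(sampling_times_h = c(2, 1)),
               "increasing")
  expect_error(simulation_design(intra_cv = -0.1), "nonnegative")
})
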