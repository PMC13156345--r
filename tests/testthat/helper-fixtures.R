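# shared fixtures: profiles are built in code, no stored data

clinical_grid <- c(0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 12)

# monoexponential decline C0 * exp(-k t) as a conc_profile
mono_profile <- function(times, C0 = 100, k = 0.2, ...) {
  conc_profile(times, C0 * exp(-k * times), ...)
}

# noise-free nicotine crossover simulation used by several files
noise_free_design <- function(n_subjects = 4, phi0 = 1, seed = 7,
                              iiv_cv = 0.3, ...) {
  simulation_design(n_subjects = n_subjects, iiv_cv = iiv_cv,
                    intra_cv = 0, prop_error_cv = 0, loq_nM = 0,
                    seed = seed,
                    activity_exposure = cyp2a6_activity(phi0), ...)
}

# metabolite profiles of one simulated subject-period
nicotine_metabolite_profiles <- function(phi = 1,
                                         times = clinical_grid,
                                         steps = c("m1_formation",
                                                   "m2_formation")) {
  p <- nicotine_params()
  prof <- simulate_profile(p, cyp2a6_activity(phi), times, steps = steps)
  list(cot = conc_profile(prof$time_h, prof$cotinine,
                          analyte = "cotinine"),
       ohc = conc_profile(prof$time_h, prof$`3-hydroxycotinine`,
                          analyte = "3-hydroxycotinine"))
}
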