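#' Parameters of the absorption/parent/metabolite cascade
#'
#' Bundles the kinetic constants of the simulated system: first-order
#' absorption from a depot (the gum or tablet), a one-compartment parent
#' drug, and up to two sequential metabolites. The CYP2A6-mediated steps
#' are the formation of metabolite 1 from the parent (fraction `f_m1` of
#' parent clearance) and of metabolite 2 from metabolite 1 (fraction
#' `f_m2` of metabolite-1 elimination).
#'
#' @param ka First-order absorption rate constant (1/h).
#' @param cl_f Apparent oral clearance of the parent (L/h).
#' @param v_f Apparent volume of distribution of the parent (L).
#' @param f_m1 Fraction of parent clearance forming metabolite 1 (0-1).
#' @param k_m1 Elimination rate constant of metabolite 1 (1/h).
#' @param f_m2 Fraction of metabolite-1 elimination forming metabolite 2
#'   (0-1).
#' @param k_m2 Elimination rate constant of metabolite 2 (1/h).
#' @param vol_ratio_m1,vol_ratio_m2 Apparent volume of each metabolite as
#'   a multiple of `v_f` (dimensionless).
#' @param dose_nmol Molar dose administered to the depot (nmol).
#' @param mw Named molar masses (g/mol) of the analytes, parent first.
#' @param analytes Analyte names, parent first; metabolites beyond
#'   `f_m1 > 0` / `f_m2 > 0` are dropped from simulated output.
#' @return An object of class `cascade_params`.
#' @seealso [nicotine_params()], [letrozole_params()], [simulate_profile()]
#' @export
cascade_params <- function(ka, cl_f, v_f, f_m1, k_m1, f_m2, k_m2,
                           vol_ratio_m1 = 1, vol_ratio_m2 = 1,
                           dose_nmol, mw, analytes) {
  stopifnot(length(analytes) == 3L, length(mw) == 3L)
  rates <- c(ka = ka, k10 = cl_f / v_f, k_m1 = k_m1, k_m2 = k_m2)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all rate constants must be positive and finite", call. = FALSE)
  if (f_m1 < 0 || f_m1 > 1 || f_m2 < 0 || f_m2 > 1)
    stop("'f_m1' and 'f_m2' must lie in [0, 1]", call. = FALSE)
  if (dose_nmol <= 0) stop("'dose_nmol' must be positive", call. = FALSE)
  if (vol_ratio_m1 <= 0 || vol_ratio_m2 <= 0)
    stop("volume ratios must be positive", call. = FALSE)
  structure(list(ka = ka, cl_f = cl_f, v_f = v_f,
                 f_m1 = f_m1, k_m1 = k_m1, f_m2 = f_m2, k_m2 = k_m2,
                 vol_ratio_m1 = vol_ratio_m1, vol_ratio_m2 = vol_ratio_m2,
                 dose_nmol = dose_nmol, mw = mw, analytes = analytes),
            class = "cascade_params")
}

#' @export
print.cascade_params <- function(x, ...) {
  cat("Cascade parameters (", x$analytes[1L], ")\n", sep = "")
  cat(sprintf("  ka %.3g /h, CL/F %.4g L/h, V/F %.4g L (k10 %.4g /h)\n",
              x$ka, x$cl_f, x$v_f, x$cl_f / x$v_f))
  cat(sprintf("  f_m1 %.3g, k_m1 %.3g /h, f_m2 %.3g, k_m2 %.3g /h\n",
              x$f_m1, x$k_m1, x$f_m2, x$k_m2))
  cat(sprintf("  dose %.5g nmol\n", x$dose_nmol))
  invisible(x)
}

# Molar masses (g/mol), standard chemistry references.
MW_NICOTINE <- 162.23
MW_COTININE <- 176.22
MW_HYDROXYCOTININE <- 192.21
MW_LETROZOLE <- 285.30

#' Default nicotine gum cascade parameters
#'
#' One-compartment nicotine (2 mg gum) with sequential cotinine and
#' trans-3'-hydroxycotinine. Parent constants come from the clinical
#' baseline endpoints the generator is calibrated against (CL/F 111 L/h,
#' terminal half-life 3.4 h, so V/F = CL/F / (ln 2 / 3.4) = 544.5 L);
#' absorption is fast (ka 6/h) to place the parent peak near 0.5 h.
#' Metabolite constants were calibrated once so the noise-free curves
#' reproduce the clinical metabolite endpoints: cotinine tmax 4 h and
#' Cmax 64 nM, metabolite ratio 0.15 at 4 h, 3-8 h partial-AUC ratio
#' about 0.2. Within a one-compartment cascade these shape targets pin
#' the *effective* metabolite disposition inside the 12-h sampling
#' window (k_m1 0.35/h, k_m2 0.25/h), which is faster than the
#' literature terminal half-life of plasma cotinine; see the package
#' vignette for the reasoning and consequences.
#'
#' @param dose_mg Nicotine dose (mg); the default 2 mg gum.
#' @return A [cascade_params()] object.
#' @export
nicotine_params <- function(dose_mg = 2) {
  cl_f <- 111
  t_half <- 3.4
  cascade_params(
    ka = 6, cl_f = cl_f, v_f = cl_f / (log(2) / t_half),
    f_m1 = 0.75, k_m1 = 0.35, f_m2 = 0.20, k_m2 = 0.25,
    vol_ratio_m1 = 0.0726, vol_ratio_m2 = 0.0668,
    dose_nmol = dose_mg * 1e6 / MW_NICOTINE,
    mw = c(nicotine = MW_NICOTINE, cotinine = MW_COTININE,
           `3-hydroxycotinine` = MW_HYDROXYCOTININE),
    analytes = c("nicotine", "cotinine", "3-hydroxycotinine"))
}

#' Default letrozole cascade parameters
#'
#' One-compartment letrozole (2.5 mg tablet), no simulated metabolites.
#' CL/F 2.16 L/h and terminal half-life 46 h give V/F = 143.4 L.
#'
#' @param dose_mg Letrozole dose (mg); the default 2.5 mg tablet.
#' @return A [cascade_params()] object.
#' @export
letrozole_params <- function(dose_mg = 2.5) {
  cl_f <- 2.16
  t_half <- 46
  cascade_params(
    ka = 1.5, cl_f = cl_f, v_f = cl_f / (log(2) / t_half),
    f_m1 = 0, k_m1 = 1, f_m2 = 0, k_m2 = 1,
    dose_nmol = dose_mg * 1e6 / MW_LETROZOLE,
    mw = c(letrozole = MW_LETROZOLE, m1 = NA_real_, m2 = NA_real_),
    analytes = c("letrozole", "m1", "m2"))
}

#' CYP2A6 activity factor
#'
#' A multiplicative activity factor phi(t) in (0, 1] applied to the
#' CYP2A6-mediated steps of the cascade during the exposure period.
#' `constant` keeps phi at `phi0`. `recovering` starts inhibited and
#' returns toward full activity as inactivated enzyme is resynthesised:
#' phi(t) = 1 - (1 - phi0) exp(-k_change t). `progressive` starts near
#' full activity and declines toward `phi0` as inactivation accrues over
#' the sampling day: phi(t) = phi0 + (1 - phi0) exp(-k_change t).
#'
#' @param phi0 Baseline-relative activity at dose time (constant mode)
#'   or the asymptote/start the mode description gives; in [0, 1],
#'   where 0 is a complete block of the CYP2A6 steps.
#' @param mode One of `"constant"`, `"recovering"`, `"progressive"`.
#' @param k_change Rate constant of the activity change (1/h).
#' @return An object of class `cyp2a6_activity`; call it like a function
#'   of time via [activity_value()].
#' @export
cyp2a6_activity <- function(phi0 = 1,
                            mode = c("constant", "recovering", "progressive"),
                            k_change = 0) {
  mode <- match.arg(mode)
  if (!is.numeric(phi0) || length(phi0) != 1L || phi0 < 0 || phi0 > 1)
    stop("'phi0' must lie in [0, 1] (0 = complete block)", call. = FALSE)
  if (k_change < 0) stop("'k_change' must be nonnegative", call. = FALSE)
  if (mode != "constant" && k_change == 0)
    stop("time-varying modes need 'k_change' > 0", call. = FALSE)
  structure(list(phi0 = phi0, mode = mode, k_change = k_change),
            class = "cyp2a6_activity")
}

#' Evaluate a CYP2A6 activity factor at given times
#'
#' @param activity A [cyp2a6_activity()] object.
#' @param t Times (h).
#' @return phi(t), in (0, 1].
#' @export
activity_value <- function(activity, t) {
  stopifnot(inherits(activity, "cyp2a6_activity"))
  with(activity, switch(mode,
    constant    = rep(phi0, length(t)),
    recovering  = 1 - (1 - phi0) * exp(-k_change * t),
    progressive = phi0 + (1 - phi0) * exp(-k_change * t)))
}

#' @export
print.cyp2a6_activity <- function(x, ...) {
  cat(sprintf("CYP2A6 activity: mode %s, phi0 %.3g", x$mode, x$phi0))
  if (x$mode != "constant") cat(sprintf(", k_change %.3g /h", x$k_change))
  cat("\n")
  invisible(x)
}

#' Simulate a noise-free concentration-time profile
#'
#' Runs the cascade for one subject-period and returns plasma
#' concentrations (nM) of the parent and, where formed, the two
#' metabolites. The activity factor multiplies the CYP2A6-mediated rate
#' constants of the selected `steps`: "m1_formation" scales the
#' parent-to-metabolite-1 formation clearance (so total parent
#' elimination becomes k10 (f_m1 phi + 1 - f_m1)), and "m2_formation"
#' scales the metabolite-1-to-metabolite-2 step analogously. Constant
#' activity uses the closed-form Bateman solution; time-varying activity
#' integrates the cascade with a fixed-step fourth-order Runge-Kutta
#' scheme (step at most 0.01 h).
#'
#' @param params A [cascade_params()] object.
#' @param activity A [cyp2a6_activity()] object; default full activity.
#' @param times Sampling times (h), positive increasing.
#' @param steps Which CYP2A6-mediated steps the activity multiplies.
#' @param cl_f,v_f Optional subject-level overrides of the population
#'   clearance and volume (used by the crossover generator).
#' @return Data frame with columns `time_h`, one concentration column per
#'   emitted analyte (nM), and attribute `amounts` holding the nmol
#'   amounts in depot/parent/metabolite compartments.
#' @export
simulate_profile <- function(params, activity = cyp2a6_activity(),
                             times,
                             steps = c("m1_formation", "m2_formation"),
                             cl_f = params$cl_f, v_f = params$v_f) {
  stopifnot(inherits(params, "cascade_params"),
            inherits(activity, "cyp2a6_activity"))
  steps <- match.arg(steps, several.ok = TRUE)
  if (any(times <= 0) || is.unsorted(times, strictly = TRUE))
    stop("'times' must be positive and strictly increasing", call. = FALSE)
  k10 <- cl_f / v_f
  on1 <- "m1_formation" %in% steps
  on2 <- "m2_formation" %in% steps

  if (activity$mode == "constant") {
    phi <- activity$phi0
    p1 <- if (on1) phi else 1
    p2 <- if (on2) phi else 1
    k10_eff <- k10 * (params$f_m1 * p1 + 1 - params$f_m1)
    km1_eff <- params$k_m1 * (params$f_m2 * p2 + 1 - params$f_m2)
    amounts <- bateman_chain(
      rates = c(params$ka, k10_eff, km1_eff, params$k_m2),
      amount0 = params$dose_nmol, times = times,
      transfer = c(params$ka, params$f_m1 * p1 * k10,
                   params$f_m2 * p2 * params$k_m1))
  } else {
    amounts <- .cascade_rk4(params, activity, times, k10, on1, on2)
  }

  conc <- cbind(amounts[, 2L] / v_f,
                amounts[, 3L] / (params$vol_ratio_m1 * v_f),
                amounts[, 4L] / (params$vol_ratio_m2 * v_f))
  keep <- c(TRUE, params$f_m1 > 0, params$f_m1 > 0 && params$f_m2 > 0)
  out <- data.frame(time_h = times, conc[, keep, drop = FALSE])
  names(out) <- c("time_h", params$analytes[keep])
  attr(out, "amounts") <- amounts
  out
}

# fixed-step RK4 for time-varying activity; state = nmol in
# (depot, parent, m1, m2)
.cascade_rk4 <- function(params, activity, times, k10, on1, on2,
                         h_max = 0.01) {
  deriv <- function(t, x) {
    phi <- activity_value(activity, t)
    p1 <- if (on1) phi else 1
    p2 <- if (on2) phi else 1
    k10_eff <- k10 * (params$f_m1 * p1 + 1 - params$f_m1)
    km1_eff <- params$k_m1 * (params$f_m2 * p2 + 1 - params$f_m2)
    c(-params$ka * x[1L],
      params$ka * x[1L] - k10_eff * x[2L],
      params$f_m1 * p1 * k10 * x[2L] - km1_eff * x[3L],
      params$f_m2 * p2 * params$k_m1 * x[3L] - params$k_m2 * x[4L])
  }
  x <- c(params$dose_nmol, 0, 0, 0)
  t_now <- 0
  out <- matrix(NA_real_, length(times), 4L)
  for (i in seq_along(times)) {
    span <- times[i] - t_now
    n_step <- ceiling(span / h_max)
    h <- span / n_step
    for (s in seq_len(n_step)) {
      k1 <- deriv(t_now, x)
      k2 <- deriv(t_now + h / 2, x + h / 2 * k1)
      k3 <- deriv(t_now + h / 2, x + h / 2 * k2)
      k4 <- deriv(t_now + h, x + h * k3)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t_now <- t_now + h
      if (any(x < -1e-9 * params$dose_nmol))
        stop("cascade integration produced a negative state at t = ",
             signif(t_now, 4), " h; reduce the step size", call. = FALSE)
      x[x < 0] <- 0
    }
    out[i, ] <- x
  }
  colnames(out) <- paste0("compartment_", 1:4)
  out
}
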