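#' Steady-state accumulation ratio for repeated dosing
#'
#' `1 / (1 - exp(-k tau))` with `k = ln 2 / t_half`: the ratio of
#' steady-state to single-dose exposure under a fixed dosing interval.
#'
#' @param t_half_h Elimination half-life (h), > 0.
#' @param tau_h Dosing interval (h), > 0.
#' @return Accumulation ratio (> 1 for finite inputs).
#' @examples
#' accumulation_ratio(6.7, 8)  # about 1.8
#' @export
accumulation_ratio <- function(t_half_h, tau_h) {
  if (any(t_half_h <= 0) || any(tau_h <= 0))
    stop("'t_half_h' and 'tau_h' must be positive", call. = FALSE)
  k <- log(2) / t_half_h
  1 / (1 - exp(-k * tau_h))
}

#' Inactivation parameters for the mechanistic static model
#'
#' @param fm Fraction of the object drug's clearance mediated by the
#'   inactivated enzyme (0-1).
#' @param kinact Maximal inactivation rate constant (1/h), > 0.
#' @param KI Inactivator concentration at half-maximal inactivation
#'   (same units as `I`), > 0.
#' @param I Inhibitor concentration at the enzyme (>= 0, same units as
#'   `KI`).
#' @param kdeg First-order degradation (resynthesis turnover) rate of
#'   the enzyme (1/h), > 0.
#' @return Object of class `inactivation_params`.
#' @export
inactivation_params <- function(fm, kinact, KI, I, kdeg) {
  if (fm < 0 || fm > 1) stop("'fm' must lie in [0, 1]", call. = FALSE)
  if (kinact <= 0 || KI <= 0 || kdeg <= 0)
    stop("'kinact', 'KI' and 'kdeg' must be positive", call. = FALSE)
  if (I < 0) stop("'I' must be nonnegative", call. = FALSE)
  structure(list(fm = fm, kinact = kinact, KI = KI, I = I, kdeg = kdeg),
            class = "inactivation_params")
}

#' Predicted AUC ratio under mechanism-based (time-dependent) inhibition
#'
#' The hepatic mechanistic static model for an irreversibly inactivated
#' enzyme:
#' `AUCR = 1 / (fm / (1 + kinact * I / (kdeg * (KI + I))) + (1 - fm))`.
#' The inactivation term compares maximal inactivation against enzyme
#' resynthesis; the unaffected fraction `1 - fm` bounds the ratio at
#' `1 / (1 - fm)`.
#'
#' @param p An [inactivation_params()] object.
#' @return Predicted fold-change in the object drug's AUC (>= 1);
#'   `Inf` when `fm = 1` and inactivation is unbounded.
#' @examples
#' msm_aucr_tdi(inactivation_params(fm = 0.8, kinact = 3, KI = 1,
#'                                  I = 1e9, kdeg = 0.5))
#' @export
msm_aucr_tdi <- function(p) {
  stopifnot(inherits(p, "inactivation_params"))
  occupancy <- if (is.infinite(p$I)) 1 else p$I / (p$KI + p$I)
  inact <- p$kinact / p$kdeg * occupancy
  denom <- p$fm / (1 + inact) + (1 - p$fm)
  if (denom == 0) {
    warning("fm = 1 with unbounded inactivation: AUC ratio is infinite")
    return(Inf)
  }
  1 / denom
}

#' Inhibitor concentration scaled to multiple dosing
#'
#' Multiplies a single-dose inhibitor concentration by the accumulation
#' ratio to approximate the repeated-dose exposure driving the static
#' model.
#'
#' @param I_single Single-dose inhibitor concentration.
#' @param t_half_h,tau_h Inhibitor half-life and dosing interval (h).
#' @return Scaled concentration.
#' @export
inhibitor_css <- function(I_single, t_half_h, tau_h) {
  I_single * accumulation_ratio(t_half_h, tau_h)
}

# FDA body-surface-area conversion factors
.km_factors <- c(mouse = 3, rat = 6, human = 37)

#' Human-equivalent dose from an animal NOAEL
#'
#' Body-surface-area scaling: `HED = dose * Km_species / Km_human` with
#' the standard conversion factors (mouse 3, rat 6, human 37).
#'
#' @param dose_mg_per_kg Animal dose (mg/kg), >= 0.
#' @param species One of `"mouse"`, `"rat"`, `"human"`.
#' @return Human-equivalent dose (mg/kg).
#' @examples
#' hed_from_noael(125, "mouse")  # about 10.1
#' @export
hed_from_noael <- function(dose_mg_per_kg, species) {
  if (any(dose_mg_per_kg < 0))
    stop("'dose_mg_per_kg' must be nonnegative", call. = FALSE)
  if (!species %in% names(.km_factors))
    stop("unknown species '", species, "'; supported: ",
         paste(names(.km_factors), collapse = ", "), call. = FALSE)
  dose_mg_per_kg * .km_factors[[species]] / .km_factors[["human"]]
}

#' Luminal concentration and solubility screen
#'
#' Concentration of an oral dose dissolved in a standard glass of
#' intestinal fluid, compared against the compound's aqueous solubility.
#'
#' @param dose_mg Dose (mg), >= 0.
#' @param volume_mL Fluid volume (mL), default 250 mL.
#' @param solubility_mg_per_mL Aqueous solubility (mg/mL); the default
#'   1.42 mg/mL is cinnamaldehyde's.
#' @return List with `conc_mg_per_mL` and logical `soluble` (TRUE when
#'   the luminal concentration does not exceed the solubility).
#' @examples
#' luminal_concentration(17)  # 0.068 mg/mL, soluble
#' @export
luminal_concentration <- function(dose_mg, volume_mL = 250,
                                  solubility_mg_per_mL = 1.42) {
  if (dose_mg < 0) stop("'dose_mg' must be nonnegative", call. = FALSE)
  if (volume_mL <= 0) stop("'volume_mL' must be positive", call. = FALSE)
  conc <- dose_mg / volume_mL
  list(conc_mg_per_mL = conc, soluble = conc <= solubility_mg_per_mL)
}

#' Constituent dose from per-capsule content
#'
#' @param per_capsule_mg Constituent mass per capsule (mg), >= 0.
#' @param capsules_per_dose Capsules per administered dose, >= 0.
#' @return Constituent dose (mg).
#' @examples
#' constituent_dose(4.135, 4)  # 16.54 mg, about 17 mg per 2-g dose
#' @export
constituent_dose <- function(per_capsule_mg, capsules_per_dose) {
  if (any(per_capsule_mg < 0) || any(capsules_per_dose < 0))
    stop("inputs must be nonnegative", call. = FALSE)
  per_capsule_mg * capsules_per_dose
}
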