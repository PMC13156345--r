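---
title: "Crossover drug-interaction analysis and the metabolite-ratio slope approach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crossover drug-interaction analysis and the metabolite-ratio slope approach}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrslope)
```

## The problem

A two-period crossover study asks whether a precipitant (here, a
botanical product containing the mechanism-based CYP2A6 inactivator
cinnamaldehyde) changes the exposure of CYP2A6 probe substrates.
Nicotine (2 mg gum) probes CYP2A6 through its sequential metabolites
cotinine and trans-3'-hydroxycotinine; letrozole (2.5 mg tablet) is a
second, slowly cleared substrate. Each subject is sampled at 0.5, 1,
1.5, 2, 3, 4, 6, 8, 10 and 12 h after dosing (letrozole out to 240 h),
once at baseline and once after repeated exposure to the precipitant.

The package implements the full analysis chain:

1. **Non-compartmental analysis** (NCA) of each concentration-time
   profile: Cmax and tmax, windowed AUCs, terminal slope λz with
   t~1/2~ = ln 2 / λz, AUC extrapolated to infinity, and apparent
   clearance CL/F = dose / AUC~0-∞~.
2. **Nicotine metabolite ratio** (NMR): the concentration ratio
   3-hydroxycotinine / cotinine, a phenotypic index of CYP2A6 activity,
   reported at 4, 6 and 8 h and as the ratio of 3-8 h partial AUCs.
3. **The slope approach**: because the NMR grows roughly linearly with
   time after the cotinine peak, its OLS slope against time — over all
   quantifiable points, and over the window from the cotinine tmax to
   the 3-hydroxycotinine tmax where the series lacks curvature — is a
   time-resolved measure of CYP2A6 activity. Parallel slopes between
   periods suggest no inhibition over the sampling day (or an
   inhibitor that was itself cleared); a reduced exposure-period slope
   suggests inhibition accruing with time.
4. **Paired statistics**: every endpoint is compared between periods as
   a geometric mean ratio (GMR), `exp` of the mean within-subject log
   difference, with a 90% t-interval and a paired t-test. No
   interaction is declared when the whole interval lies inside the
   closed no-effect range 0.80-1.25.
5. **Static predictions**: the accumulation ratio 1/(1-e^(-kτ)), the
   hepatic mechanistic static model for time-dependent inhibition,
   NOAEL-to-human-equivalent-dose scaling, and a luminal
   concentration/solubility screen.

Individual plasma concentrations for such studies are rarely published,
so the package ships a synthetic-study generator that reproduces the
kinetic and statistical structure the analysis assumes; every stage is
testable against simulation truth.

## The cascade model behind the generator

A dose D (nmol) placed in a depot moves through a linear chain:

depot →(ka) parent →(f~m1~·k~10~) metabolite 1 →(f~m2~·k~m1~) metabolite 2

Each compartment empties with a first-order rate constant (ka, k~10~ =
CL/F / V/F, k~m1~, k~m2~); the fractions f~m1~ and f~m2~ of the two
CYP2A6-mediated steps feed the next compartment and the remainder
leaves the chain. Amounts follow the classical Bateman
sum-of-exponentials solution; `bateman_chain()` evaluates it directly
and switches to an exact matrix-exponential evaluation of the cascade
rate matrix when two rate constants fall within a relative 1e-8 of each
other, where the sum is numerically singular (the matrix exponential is
valid for repeated roots, so no special-cased limit formulas are
needed). Concentrations divide amounts by the apparent volumes: V/F for
the parent, `vol_ratio_m1` · V/F and `vol_ratio_m2` · V/F for the
metabolites.

A CYP2A6 activity factor φ(t) ∈ [0, 1] multiplies the CYP2A6-mediated
*formation clearances* during the exposure period, so reduced activity
both slows metabolite input and (through f~m1~) lowers total parent
clearance, as mechanism dictates. Three shapes cover the study
narratives: constant; *recovering*, φ(t) = 1 - (1 - φ0)e^(-k·t)
(inactivated enzyme resynthesised after a cleared inhibitor); and
*progressive*, φ(t) = φ0 + (1 - φ0)e^(-k·t) (inactivation accruing over
the sampling day). Constant activity keeps the closed form; time-varying
activity integrates the cascade with fixed-step RK4 at 0.01 h, aborting
if a state goes negative.

`simulate_profile()` lets the caller choose which CYP2A6 steps φ
multiplies. The default is both, matching mechanism. One documented
subtlety: with φ on both steps, slowing parent clearance reshapes the
cotinine curve, so the NMR slope is proportional to φ only
approximately (at φ = 0.8 the slope GMR is about 0.73, within 15% of
0.8; at φ = 0.5 it under-recovers to about 0.36). With φ restricted to
the cotinine → 3-hydroxycotinine step the slope is proportional to φ
within a few percent across 0.5-1.0, which is the cleanest way to see
that the slope tracks the step it is meant to phenotype.

## Default parameters and their calibration

The clinical literature reports endpoints, not micro-constants, so the
generator's defaults were calibrated once against the baseline
endpoints of the study population and then frozen.

Nicotine (`nicotine_params()`): CL/F = 111 L/h and t~1/2~ = 3.4 h give
k~10~ = 0.204 /h and V/F = 544.5 L; ka = 6 /h puts the parent peak near
0.5 h; the 2-mg dose is 12,328 nmol. f~m1~ = 0.75 reflects the dominant
cotinine pathway. The metabolite constants (k~m1~ = 0.35 /h, k~m2~ =
0.25 /h, f~m2~ = 0.20, volume ratios 0.0726 and 0.0668) reproduce the
observed cotinine peak (64 nM at 4 h), the NMR of 0.15 at 4 h, and a
3-8 h partial-AUC ratio of about 0.2. Within a one-compartment cascade
the observed cotinine tmax of 4 h *requires* an effective within-window
cotinine disposition faster than plasma cotinine's literature terminal
half-life (~16 h): cotinine tmax depends only on (ka, k~10~, k~m1~),
and a 16-h half-life would place the simulated peak near 10 h, leaving
the slope window with fewer than three sampling points. The defaults
therefore honour the observed 12-h-window shape at the cost of the
(unsampled) later terminal phase. One visible consequence: the
simulated NMR rises more steeply (slope ≈ 0.04 /h) than the clinical
0.022-0.024 /h, because the real multiphasic cotinine disposition is
compressed into a single phase. No endpoint used by the tests depends
on the absolute slope, only on ratios between periods, which the
simulation preserves.

Letrozole (`letrozole_params()`): one compartment, CL/F = 2.16 L/h,
t~1/2~ = 46 h (V/F = 143.4 L), ka = 1.5 /h, 2.5 mg = 8763 nmol, no
simulated metabolites. The published sampling schedule lists draws "up
to 240 hours" without times; `letrozole_times()` extends the 12-h grid
with 24, 48, 72, 96, 120, 168 and 240 h, a conventional follow-up
ladder for a two-day half-life.

Variability (`simulation_design()`): inter-subject CV 0.30 on CL/F and
V/F (the width of the reported baseline clearance intervals implies
roughly 27-30%), intra-subject (period) CV on clearance 0.26 for
nicotine and 0.16 for letrozole — the values the study's own sample-size
computations assume — and proportional assay noise CV 0.10 (the
bioanalytical method reports <10% variability). All deviates are
log-normal with median 1. LOQ defaults derive from the assay
calibration floors: 1.2 ng/mL per nicotine-cascade analyte
(`nicotine_loq_nM()`, e.g. 7.40 nM for nicotine) and 1.56 nM for
letrozole; values strictly below the LOQ are censored and treated as
missing, values exactly at it are retained. All draws flow from one
seeded generator in a fixed order, so datasets are bit-reproducible.

What the generator does *not* emulate: multi-compartment distribution
(see limitations), enterohepatic recirculation, the 30-minute
chew-and-park gum procedure (absorption is plain first-order),
genotype classes (the continuous φ subsumes them), and
concentration-dependent assay error. Passing tests therefore show the
analysis chain is correct under the stated kinetic model, not that the
model captures every feature of real plasma data.

## Numerical and statistical conventions

* **AUC rule**: linear-up/log-down trapezoid — linear where
  concentration is non-decreasing across a segment or touches zero,
  logarithmic `(C1-C2)/ln(C1/C2)·Δt` where strictly decreasing. The
  pure-linear rule is available via `method = "linear"`. Window
  endpoints off the grid are interpolated under the same rule; interior
  censored points are bridged; a window starting at 0 before the first
  sample is anchored at C(0) = 0 (single extravascular dose); there is
  no extrapolation past the last quantifiable point. Predose samples
  are treated as the t = 0 baseline and excluded when zero or censored.
* **Terminal slope**: OLS of ln C on t over the last 3, 4, ...
  quantifiable points strictly after tmax; the candidate set maximising
  adjusted R² with a positive elimination rate wins. Fewer than three
  declining points leave t~1/2~, AUC~0-∞~ and CL/F missing rather than
  forced. An extrapolated AUC fraction above 20% raises a reliability
  flag, not an error.
* **Partial-AUC ratio convention**: the 3-8 h row is the ratio of the
  two metabolites' partial AUCs (the methods compute a partial AUC "for
  each metabolite"); the alternative reading — time-averaged AUC of the
  ratio series — is available via `convention = "auc_of_ratio"` and
  lands within a few percent on smooth profiles.
* **Slope window edge cases**: if the 3-hydroxycotinine tmax falls at
  the last quantifiable time the window simply ends there; a window
  holding fewer than three NMR points leaves `slope_linear` missing.
  Pattern classification calls slopes parallel within a relative 0.10
  of the slope ratio — the clinical read is visual, so the numeric
  default is a package choice.
* **GMR machinery**: log-scale t-intervals throughout; the no-effect
  bounds are treated as a closed interval; subjects missing either
  period are excluded listwise per endpoint; a zero-variance set of
  within-subject ratios reports a degenerate zero-width interval and,
  for a nonzero shift, no p-value. tmax is summarised as median
  (min-max) only — no test, matching practice.
* **Sample size and power**: the design numbers (16 subjects at CV 26%
  for 80% power; >90% power at 10 subjects and CV 16%; Δ = 20%, α =
  0.05 two-sided) are reproduced by the proportional-scale effect size
  d = Δ/CV with noncentral-t power at df = n - 1 and noncentrality
  d·√n. The log-scale convention (d = ln(1+Δ)/√ln(1+CV²)) is exposed
  via `scale = "log"` but is not the default because it does not
  reproduce the printed sample sizes.
* **Confluent rates**: the Bateman sum switches to the matrix
  exponential when |k~i~ - k~j~| < 1e-8 · max(k); tests pin continuity
  with the distinct-rate branch and the known k·t·e^(-kt) repeated-root
  solution.
* **Static-model conventions**: the mechanistic static model implements
  the hepatic time-dependent-inhibition term only, AUCR = 1 / (fm / (1
  + kinact·I/(kdeg·(KI+I))) + (1 - fm)); competitive and intestinal
  terms are out of scope. Human-equivalent doses use the standard
  body-surface-area factors (mouse 3, rat 6, human 37). Inhibitor
  accumulation to steady state multiplies a single-dose concentration
  by `accumulation_ratio()`.

## Worked example

```{r example, eval = FALSE}
design <- simulation_design(
  n_subjects = 16, intra_cv = 0.26, prop_error_cv = 0.10,
  loq_nM = nicotine_loq_nM(), seed = 14,
  activity_exposure = cyp2a6_activity(0.5))
study <- simulate_crossover_study(design, nicotine_params())

fit <- crossover_ddi(
  study,
  auc_windows = list(nicotine = list(c(0, 4)),
                     cotinine = list(c(0, 12)),
                     `3-hydroxycotinine` = list(c(0, 12))),
  nmr_analytes = c("cotinine", "3-hydroxycotinine"))
fit
```

A halved constant activity raises nicotine AUC (slower clearance),
lowers the cotinine and 3-hydroxycotinine exposures and pulls the slope
GMR below one; at full activity every GMR interval sits inside
0.80-1.25.

## Problem sizes in the test suite

The suite runs the Monte-Carlo checks at sizes chosen to give stable
verdicts in well under the tolerance widths: 20 random cascades against
the ODE oracle; 1000 simulated crossovers of 16 subjects for the 90%
CI coverage check (±3 percentage points); 50 noise-free subjects for
the activity-recovery check; 10,000-20,000 replicates for the power
comparisons (Monte-Carlo standard error ≈ 0.3 percentage points).

## Known limitations

* **Letrozole Cmax**: with the clinical clearance and half-life, a
  one-compartment model bounds Cmax at D·k/CL ≈ 61 nM for any
  absorption rate — below the observed 87 nM, which reflects a
  distribution phase the model deliberately omits. Simulated letrozole
  therefore matches t~1/2~ and CL/F closely but under-predicts Cmax by
  about a third; the corresponding calibration test records this
  honestly rather than hiding it.
* **NMR slope magnitude** is steeper than clinical (above); period
  *ratios* of the slope, the quantity the analysis compares, are
  unaffected to first order.
* **No sequence or period effects**: the generator draws period
  deviates symmetrically and the analysis is a pure paired comparison;
  mixed-effects modelling of sequence effects is out of scope.
* The fixed-tolerance pattern classifier is a convenience for simulated
  data; clinical use of the slope approach should inspect the per
  subject NMR-time plots (`plot()` on an `nmr_slope_fit`).
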