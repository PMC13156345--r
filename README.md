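# nmrslope

Crossover pharmacokinetic drug-interaction analysis for CYP2A6 probe
substrates, including the nicotine-metabolite-ratio **slope approach**.

## What it is for

Clinical pharmacologists running (or re-analysing) two-period crossover
interaction studies need the same chain of tools every time: per-profile
non-compartmental analysis, metabolite-ratio phenotyping, paired
geometric-mean-ratio statistics against regulatory no-effect bounds, and
the desk-side static calculations that motivate or contextualise the
study. `nmrslope` packages that chain for studies built around nicotine
(with its sequential CYP2A6-derived metabolites cotinine and
trans-3'-hydroxycotinine) and letrozole, together with a fully
reproducible synthetic-study generator, since individual plasma
concentrations from such trials are rarely published.

The core quantities, in the field's standard notation:

* **NCA**: C~max~, t~max~, windowed AUC by the linear-up/log-down
  trapezoid, terminal slope λ~z~ (best-fit log-linear regression,
  adjusted-R² point selection), t~1/2~ = ln 2/λ~z~,
  AUC~0-∞~ = AUC~0-tlast~ + C~last~/λ~z~, CL/F = dose/AUC~0-∞~.
* **NMR**: the nicotine metabolite ratio
  [3-hydroxycotinine]/[cotinine] at 4, 6, 8 h and as a 3-8 h
  partial-AUC ratio.
* **Slope approach**: the OLS slope of NMR vs. time over all
  quantifiable points and over the most linear window — from the
  cotinine t~max~ to the 3-hydroxycotinine t~max~ — compared between
  periods as a GMR. Parallel slopes suggest no inhibition across the
  sampling day; a reduced slope suggests inhibition accruing with time.
* **Paired statistics**: GMR = exp(mean ln(exposure/baseline)) with a
  90% t-interval; no interaction iff the whole interval lies in the
  closed range 0.80-1.25; noncentral-t power and sample size for the
  paired design (effect size d = Δ/CV, noncentrality d·√n).
* **Static predictions**: accumulation ratio 1/(1-e^(-kτ)); the hepatic
  mechanistic static model for time-dependent inhibition
  AUCR = 1/(f~m~/(1 + k~inact~·I/(k~deg~·(K~I~+I))) + (1-f~m~));
  NOAEL → human-equivalent dose by body-surface-area factors; luminal
  concentration/solubility screening.
* **Simulation**: closed-form Bateman cascade (depot → parent →
  metabolite 1 → metabolite 2) with log-normal inter-subject and
  period variability, proportional assay noise, LOQ censoring, and a
  constant or time-varying CYP2A6 activity factor applied in the
  exposure period.

## Worked example

Simulate a 16-subject crossover in which the precipitant holds CYP2A6
at 80% of baseline activity, then run the full analysis:

```r
library(nmrslope)

design <- simulation_design(
  n_subjects = 16, intra_cv = 0.26, prop_error_cv = 0.10,
  loq_nM = nicotine_loq_nM(), seed = 14,
  activity_exposure = cyp2a6_activity(0.8))
study <- simulate_crossover_study(design, nicotine_params())

fit <- crossover_ddi(
  study,
  auc_windows = list(nicotine = list(c(0, 4)),
                     cotinine = list(c(0, 12)),
                     `3-hydroxycotinine` = list(c(0, 12))),
  nmr_analytes = c("cotinine", "3-hydroxycotinine"))
fit
```

```
Crossover interaction analysis (90% CI, no-effect 0.8-1.25)
Subjects: 16 analysed, 0 excluded (missing period)

Endpoint                           n Baseline GM (CI)       exposure GM (CI)       exposure/Baseline (CI) p        decision
cotinine Cmax                     16 46.6 (38.9-55.9)       36.6 (29.6-45.2)       0.784 (0.697-0.882)  0.0025   interaction_possible
cotinine AUC0-12                  16 397 (336-468)          327 (268-397)          0.824 (0.758-0.895)  0.001    interaction_possible
nicotine Cmax                     16 18.8 (16.7-21.3)       19.9 (17.8-22.4)       1.06 (1.01-1.11)     0.0611   no_interaction
nicotine AUC0-4                   15 56.5 (50.3-63.4)       60.9 (54.7-67.8)       1.08 (1.03-1.13)     0.0155   no_interaction
nicotine CL/F                     16 83.4 (67.6-103)        62.9 (54.9-72.1)       0.755 (0.615-0.927)  0.0298   interaction_possible
NMR nmr_6h                         6 0.219 (0.191-0.251)    0.159 (0.147-0.172)    0.728 (0.607-0.873)  0.0168   interaction_possible
NMR slope_all                      8 0.0364 (0.033-0.0402)  0.0217 (0.0169-0.0277) 0.595 (0.469-0.755)  0.0043   interaction_possible
...
tmax, median (min-max), h:
  nicotine                 baseline  0.5 (0.5-1.5)
  nicotine                 exposure  1.25 (0.5-2)
```

(Excerpt; the full report also carries 3-hydroxycotinine endpoints,
AUC~0-∞~, t~1/2~ and the remaining NMR rows.) Reading it: the
partially inhibited exposure period leaves nicotine C~max~ and AUC~0-4~
inside the no-effect range but lowers the metabolite exposures and the
NMR slope GMR well below one — the downstream, metabolite-side
endpoints are the sensitive detectors of a modest CYP2A6 effect.

Desk-side numbers:

```r
sample_size_paired(cv = 0.26)            # 16 subjects for 80% power
power_paired(n = 10, cv = 0.16)          # 0.939 at the letrozole CV
round(accumulation_ratio(6.7, 8), 2)     # 1.78-fold accumulation
hed_from_noael(125, "mouse")             # 10.1 mg/kg human equivalent
```

## Learning more

The vignette (`vignettes/slope-approach.Rmd`) documents the cascade
model, the calibration of the default parameters, every numerical
convention (trapezoid rules, λ~z~ selection, LOQ handling, confluent
rate constants), the statistical conventions, and the known
limitations of the one-compartment simulator.
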