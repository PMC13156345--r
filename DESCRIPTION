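Package: nmrslope
Title: Crossover Pharmacokinetic Drug-Interaction Analysis and the
    Nicotine-Metabolite-Ratio Slope Approach
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-dose crossover drug-drug interaction studies
    of CYP2A6 probe substrates. Provides non-compartmental analysis of
    concentration-time profiles (Cmax, tmax, windowed and extrapolated AUC
    by the linear-up/log-down trapezoid, terminal slope, CL/F), the
    nicotine metabolite ratio (3-hydroxycotinine/cotinine) at fixed times,
    its 3-8 h partial-AUC ratio, and the "slope approach" that regresses
    the metabolite ratio on time over all points and over the most linear
    window. Paired crossover statistics compute geometric means and
    geometric mean ratios with 90% confidence intervals, the 0.80-1.25
    no-effect decision, and noncentral-t sample-size and power for the
    paired design. A synthetic-study generator built on closed-form
    Bateman cascade kinetics (depot, parent, two sequential metabolites,
    with a tunable CYP2A6 activity factor) supplies fully reproducible
    two-period crossover datasets, and static drug-interaction calculators
    (accumulation ratio, mechanistic static model for time-dependent
    inhibition, NOAEL-to-human-equivalent dose, luminal solubility screen)
    cover translational predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    grDevices,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
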