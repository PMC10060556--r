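Package: icpwave
Title: Coupled Lumped-Parameter Simulation of Intracranial Pressure and
    Cerebral Photoplethysmography Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation of the cardiocerebral arterial circulation as a
    lumped-parameter (Windkessel) hydraulic circuit, coupled to an intracranial
    pressure (ICP) compartment with cerebrospinal-fluid formation and outflow,
    and to per-territory microcirculation circuits whose capacitor transmural
    pressures yield a simulated photoplethysmography (PPG) signal.  Includes
    age-dependent nonlinear aortic and carotid capacitance laws, a piecewise
    pressure-dependent intracranial capacitance with a capacitance-reduction
    ratio, stiff time integration, waveform-feature extraction (pulsatility
    index, resistive index, max-to-mean ratio, rising time), and a scenario
    grid over age, capacitance reduction and cerebral perfusion territory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
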