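Package: vibronica
Title: Surface-Hopping Dynamics and Ensemble Spectroscopy on Linear
    Vibronic Coupling Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-contained toolkit for semiclassical nonadiabatic
    photodynamics on model potentials: normal-mode analysis of Cartesian
    Hessians with translation/rotation projection, classical normal-mode
    and quantum (ground-state and thermal) Wigner initial-condition
    sampling, linear vibronic coupling (LVC) model Hamiltonians with
    analytic adiabatic energies, gradients and nonadiabatic couplings,
    Tully fewest-switches surface hopping with time-derivative couplings
    from either analytic coupling vectors or wave-function overlaps
    (Hammes-Schiffer-Tully), and nuclear-ensemble steady-state and
    transient spectra with photolysis-rate integration and rate-equation
    population kinetics.  Everything runs on synthetic model systems with
    no electronic-structure engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
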