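Package: iltraj
Title: Trajectory Analysis of Hydrogen Bonding, Transport and Cellulose
    Solvation in Ionic Liquids
Version: 0.1.0
Authors@R:
    person("iltraj", "developers", email = "iltraj@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for molecular dynamics trajectories of
    ionic-liquid cellulose solvents. Reads multi-frame XYZ and LAMMPS text
    dump trajectories with periodic boxes, computes radial and spatial
    distribution functions in local molecular frames, detects hydrogen
    bonds under a geometric O...H distance criterion, estimates
    intermittent hydrogen-bond lifetimes from occupancy autocorrelation,
    summarises the hydrogen-bond network topology as donor/acceptor flow
    (Sankey) tables, derives self-diffusion coefficients from mean squared
    displacement, estimates solvation enthalpies from potential-energy
    traces, and calibrates a logarithmic model mapping solvation enthalpy
    to cellulose solubility. Ships synthetic-data generators with known
    ground truth (ideal gas, Brownian motion, two-state telegraph hydrogen
    bonds, ring-stacked pairs, Gaussian energy traces, log-law solubility
    points) so every stage is testable without running MD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
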