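Package: poregate
Title: Free-Energy, Kinetic and Titration Analysis of Gated Membrane Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics studies of pH-gated
    membrane channels such as the aquaglyceroporins. Estimates
    one-dimensional potentials of mean force from umbrella-sampling windows
    by the weighted histogram analysis method (WHAM) with bootstrap error
    bands, converts barrier heights into Kramers-style permeation rates and
    solute rate ratios, counts complete channel traversals in trajectories,
    fits Henderson-Hasselbalch titration curves to constant-pH protonation
    traces to obtain apparent pKa values and deprotonation free-energy
    shifts, estimates alchemical free-energy differences from
    forward/backward nonequilibrium work values via Bennett's acceptance
    ratio, computes contact and ring-stacking propensities and solute
    density clusters, and profiles pore radii of channel structures by
    sphere squeezing. A synthetic-data module generates every input class
    (overdamped Langevin traces in analytic potentials, two-state
    protonation chains, Crooks-consistent work distributions, toy pore
    structures) with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    bio3d,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
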