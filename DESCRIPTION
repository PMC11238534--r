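Package: bindcp
Title: Heat Capacity Changes in Protein-Ligand Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and analysis of heat capacity changes (delta Cp) upon
    protein-ligand binding. Implements the four-system energy-derivative
    estimator of binding delta Cp from molecular dynamics energy time series
    (holoprotein, apoprotein, ligand in water, pure water), the
    mandatory-coupling conformational-equilibrium model for apparent binding
    enthalpy, free energy and heat capacity with fitting to calorimetric
    (ITC-style) data, conformational and fluctuation analyses of coordinate
    ensembles (end-to-end distance distributions, distance-binned energy
    profiles, iterative ensemble superposition, RMSD, RMSF, B-factor
    conversion), and synthetic-data generators emulating the statistical
    structure of molecular dynamics output so every stage is testable without
    simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
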