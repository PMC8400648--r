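Package: tgtrend
Title: Trend-Shift Glass Transition Analysis for Molecular Dynamics of
    Amorphous Drug Dispersions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for vitrification studies of amorphous
    drug-excipient dispersions from molecular dynamics trajectories.
    Reads LAMMPS text dumps, extended-XYZ trajectories and thermodynamic
    tables; computes mean-squared displacements and Einstein
    self-diffusivities, mass densities, molar and excess volumes,
    site-site radial distribution functions and hydrogen-bond contact
    statistics, and vaporization/fusion energetics.  The central
    estimator locates the glass transition temperature as the break
    point of density and self-diffusivity temperature scans by
    continuous two-segment (hinge) weighted regression with
    delta-method uncertainty propagation, and combines the two
    branches.  Includes empirical mixture rules (Gordon-Taylor, Fox,
    fusion-temperature fraction), a compiled binary Lennard-Jones
    glass-former for end-to-end testing, synthetic trajectory and
    thermal-scan generators with known ground truth, and validation
    reporting against bundled experimental comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
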