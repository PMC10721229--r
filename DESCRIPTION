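Package: mabsolkit
Title: Solution Biophysics of Antibody Fragments: Structure, Double Layer,
    PMF and Virial Coefficients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-simulation and experimental-fit analysis for proteins
    (typically IgG Fab/Fc fragments) in electrolyte solution. Computes
    per-frame size and shape metrics (radius of gyration, principal-axis
    dimensions, solvent-accessible surface area), surface-minimum-distance
    radial distribution functions with coordination numbers and residence
    statistics, net-charge profiles of the ionic double layer with
    exponential (Debye) decay fits and the Poisson-Boltzmann closed form,
    weighted-histogram (WHAM) reconstruction of protein-protein potentials
    of mean force from umbrella-sampling windows, second osmotic virial
    coefficients B22 from PMFs, and the experimental-side estimators:
    Guinier analysis of small-angle scattering curves and Debye-plot
    regression of static light scattering series. A synthetic-data module
    generates every input with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
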