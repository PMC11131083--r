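Package: drygel
Title: Pore Formation in Drying Core-Shell Hydrogel Spheres
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled moisture-transport and large-deformation model of a drying
    spherical hydrogel (a proxy for fruit and vegetable tissue) with a stiff
    elastic skin and a gas-filled central cavity. Stress and chemical potential
    derive from a Neo-Hookean / Cloizeaux-scaling free energy; the gas cavity
    couples through vapour equilibrium and the ideal gas law. Three mutually
    validating solvers are provided: a closed-form steady-state approximation
    for core-shell spheres, a transient and steady finite-volume scheme on a
    mesh co-moving with the polymer network, and a 1D spherical mixed
    finite-element solver of the weak formulation with Robin boundary fluxes
    and a cavity vapour ODE. Experiment runners reproduce cross-solver
    comparisons, the critical skin-stiffness scan, pore-size scans, and
    transient drying studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
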