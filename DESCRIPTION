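Package: triswell
Title: Triphasic Mechano-Electrochemical Finite Elements for Cartilage Free Swelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-dimensional mechano-electrochemical (triphasic) finite-element
    simulation of articular cartilage free swelling. The tissue is modelled as a
    charged hydrated mixture of an incompressible elastic solid matrix, water,
    and two monovalent ion species (Na+ and Cl-), with Donnan osmotic pressure
    generated by the fixed charge density of the extracellular matrix. The
    package provides the pointwise constitutive laws, Donnan equilibrium and an
    analytic confined-swelling steady-state oracle, trilinear hexahedral
    assembly of the coupled weak form in the unknowns (u, eps_w, eps_plus,
    eps_minus), Crank-Nicolson time stepping with Newton iteration, packaged
    free-swelling scenarios (quasi-1D validation, full 3D sample, parameter
    sweeps over fixed charge density, porosity, and osmotic coefficient),
    swelling-phase segmentation, and CSV/VTK output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
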