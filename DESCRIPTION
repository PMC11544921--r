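Package: fruitdrop
Title: Multiscale Finite Element Simulation of Fruit Drop-Impact Bruising
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Explicit-dynamics finite element simulation of fruit drop impacts
    and the bruise-susceptibility analysis built on top of it. The package
    generates a parametric multiscale kiwifruit solid (skin membrane, flesh,
    core) as a conformal tetrahedral mesh, integrates the impact against a
    planar surface with a lumped-mass central-difference scheme, J2 bilinear
    elastoplasticity with radial return and elastic-foundation penalty contact,
    extracts bruised volume and absorbed energy under a Von Mises yield
    criterion, and fits quadratic response-surface models of bruise
    susceptibility (bruised volume per unit absorbed energy) over drop height
    and collision angle for different contact surface materials. Includes
    force-displacement data reduction to bilinear constitutive parameters and
    the published response-surface prediction polynomials for steel, PVC and
    neoprene surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
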