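Package: cellfile
Title: Multiscale Modelling of Hormone Transport Along Plant Cell Files
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete multicellular and homogenised continuum models of
    hormone (e.g. gibberellin) transport along a file of plant cells with
    cytoplasmic, vacuolar and apoplastic compartments.  Membrane fluxes
    combine passive diffusion of the protonated hormone with
    Goldman-Hodgkin-Katz carrier transport of the anion; the package
    computes the resulting effective permeabilities, simulates the full
    5N-2 compartmental ODE system (including growing, spatially graded and
    synchronously dividing cell files), and evaluates the matching
    tissue-scale effective diffusivity, advective velocity and dilution
    coefficients of the reaction-advection-diffusion limit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
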