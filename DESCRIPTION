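Package: actinME
Title: Master-Equation Models of Force-Generating Branched Actin Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Deterministic master-equation (ME) simulation of dendritic
    (Arp2/3-branched) actin networks in two dimensions and in azimuthally
    symmetric three-dimensional geometry, with branching treated as a
    directional spreading term, plus spontaneous nucleation and
    cofilin-driven severing.  The ME is validated against an explicit-filament
    stochastic simulator of network growth against a constant-force obstacle,
    and is coupled into a mechanochemical model of clathrin-mediated
    endocytosis in budding yeast: nucleation-promoting-factor (Las17)
    feedback, a molecular clutch, a pretabulated family of equilibrium
    membrane shapes under turgor pressure, and force balance between the
    pushing (ring) and pulling (spot) regions of the actin network.  Includes
    drivers for wild-type, mutant and drug-inhibition experiments, and a
    random accept-if-lower parameter-fitting routine with a synthetic
    time-course target generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
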