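Package: purinome
Title: Kinetic Modelling of Extracellular ATP Turnover in Intestinal Epithelial Cells
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven kinetic model of the extracellular purinome of
    intestinal epithelial (Caco-2-like) cells. Couples intracellular ATP
    release fluxes (basal leakage, transient non-lytic release after
    hypotonic shock, lytic release) with five ecto-enzyme rate laws
    (ecto-ATPase, ecto-ADPase, ecto-5'-nucleotidase, ecto-adenylate kinase
    and ecto-NDP kinase) in an eight-species ordinary differential
    equation system. Provides stiff integration of experimental protocols
    with timed nucleotide additions, parameter-scan uncertainty
    envelopes, initial-velocity and multi-experiment least-squares
    estimators, a registry of standard luminometry protocols, a generator
    of synthetic noisy luminometry time courses for parameter-recovery
    testing, and SBML Level 3 export of the model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
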