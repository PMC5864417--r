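Package: nitrox
Title: Dynamic Flux Balance Modeling of Nitrogen Oxide Fluxes During
    Nitrification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates complete nitrification by Nitrosomonas europaea and
    Nitrobacter winogradskyi in sealed batch vials with an integrative model
    that couples reduced stoichiometric energy models of both organisms
    (solved by linear programming at every time step, i.e. dynamic flux
    balance analysis) to abiotic nitrogen-oxide reaction kinetics, acid-base
    speciation at fixed pH, and two-film gas-liquid mass transfer.  Includes
    Monod-type substrate uptake kinetics, per-segment uptake-rate
    calibration from measured consumption curves, fitting of nitrite- and
    nitric-oxide-reductase activity bounds against headspace gas data, a
    synthetic-data generator that emulates closed-vial nitrification
    experiments, and source/sink decomposition of nitric oxide fluxes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
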