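Package: outflowEFSI
Title: Electrical-Fluid-Structure Interaction in the Aqueous Outflow Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale coupled simulation of electroosmotic aqueous-humor
    flow through an idealized trabecular meshwork / juxtacanalicular tissue /
    Schlemm's canal complex. The charged endothelial glycocalyx is modelled as
    a Debye-Huckel electric double layer on tagged boundary facets, the
    aqueous humor as incompressible laminar flow with an electric body force,
    and the outflow tissues as near-incompressible linear elastic solids,
    coupled by a partitioned (Dirichlet-Neumann) scheme over a linear
    intraocular-pressure ramp. Includes a synthetic geometry generator with
    Schlemm's canal inner-wall pore statistics, analytic electrokinetic and
    hydrodynamic oracles, scenario comparison reports, and VTK/CSV/JSON
    export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
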