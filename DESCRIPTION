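Package: samclone
Title: Probabilistic Efficacy Modelling of Ara-C Treatment in Oligoclonal
    AML with SAMHD1 Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-form probabilistic model of cytarabine (ara-C) treatment
    efficacy in acute myeloid leukaemia (AML) where SAMHD1 acts both as a
    tumour suppressor and as an ara-CTPase resistance factor. Provides
    monoclonal and oligoclonal efficacy computation, benefit thresholds and
    regime classification for adding a SAMHD1 inhibitor (symmetric or
    ara-CTPase-specific), phase-diagram grids over the parameter space,
    multi-cycle regimen simulation with clonal-fraction updating, estimation
    of the model parameters x, y and z from cell-viability tables with
    delta-method error propagation, seeded synthetic-data generators, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
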