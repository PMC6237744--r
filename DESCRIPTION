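Package: crisprCircuits
Title: Quantitative Models for dCas9-Based Genetic Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterizing CRISPRi NOT gates and predicting the
    behaviour of layered dCas9-based genetic circuits. Fits repressing Hill
    response functions to gate transfer curves, composes them into cascade
    predictions, and implements a resource-sharing (retroactivity) model in
    which competing sgRNAs titrate a finite pool of dCas9: mass-action ODE
    dynamics with a conservation law, steady-state closed forms, fitting of
    fold-repression versus competitor count, and a threshold calculator for
    the number of co-expressed sgRNAs a circuit can sustain. Also provides
    flow-cytometry summary statistics (geometric means, background
    subtraction, fold-repression), immunoblot densitometry standard-curve
    quantification of molecules per cell, ATP cost accounting for regulator
    proteins, and seeded synthetic-data generators with known ground truth
    for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'gate-response.R'
    'cascade.R'
    'resource-sharing.R'
    'cytometry.R'
    'blot-quant.R'
    'atp-cost.R'
    'synthetic-data.R'
    'io.R'
    'pipeline.R'
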