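Package: aavcogs
Title: Cost-of-Goods, Scheduling and Process Modelling for AAV Vector Manufacturing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Techno-economic and process modelling toolkit for adeno-associated
    virus (AAV) vector production. Compares manufacturing platforms (a closed
    hollow-fiber bioreactor versus multilayer flask systems) on cost per batch,
    open processing steps and production time under facility-capacity
    constraints; provides titer/yield/recovery/clearance mass-balance
    arithmetic for upstream harvests and downstream unit operations;
    face-centred central composite designs and quadratic response-surface
    fitting for lysis optimization; a perfusion lactate mass-balance estimator
    of viable cell number; and seeded synthetic-scenario generators so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
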