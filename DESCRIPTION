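Package: coroflow
Title: Closed-Loop Cardiac Mechanics and Coronary Perfusion Simulation with Demand-Driven Autoregulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lumped-parameter closed-loop simulation of ventricular mechanics
    (three-wall-segment ventricular interaction with multi-segment walls and a
    Hill-type myofiber model), systemic and pulmonary circulations, and a
    coronary network with three transmural layers per perfused wall segment.
    Regional myocardial oxygen demand is estimated from the fiber stress-strain
    area and coronary flow is regulated to demand by a vasodilator signal,
    enabling simulation of resting and hyperemic myocardial flow and flow
    reserve under synchronous activation, acute left bundle branch block, and
    chronic left bundle branch block with demand-driven remodeling of wall
    mass.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
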