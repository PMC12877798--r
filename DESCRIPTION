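Package: clotflow
Title: Coupled Hemodynamics and Coagulation Modelling of Thrombus Growth
    in Stenosed Vessels and Coronary Bifurcations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates thrombus growth and flow cessation in idealized
    two-dimensional stenosed tubes and coronary-style bifurcations. Blood
    flow is solved with a finite-volume Brinkman (porous-medium penalized
    Navier-Stokes) formulation in which the growing clot acts as a
    deposition- and fibrin-dependent hydraulic resistance. A nine-species
    convection-diffusion-reaction network (resting and activated
    platelets, ADP, thromboxane, prothrombin, thrombin, antithrombin,
    fibrinogen, fibrin) drives platelet activation and wall deposition on
    thrombogenic surfaces identified by a wall-shear-stress threshold.
    Includes synthetic vessel geometry generation from patient-style
    parameter tables, wall-shear risk classification, power-law
    regression of maximal stenotic shear stress, and a coupled
    time-stepping pipeline that detects branch flow cessation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
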