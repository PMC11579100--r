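Package: optidose
Title: Optimal Drug Dosing for PK/PD Models with Efficacy and Safety State Constraints
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes optimal drug doses (or dosing intervals) for ordinary
    differential equation based pharmacokinetic/pharmacodynamic models by
    minimizing a cost functional subject to state constraints that encode
    efficacy and safety targets. State-constrained optimal control problems
    are transformed into box-constrained optimization problems via quadratic
    (Moreau-Yosida) penalty continuation or a safeguarded
    Powell-Hestenes-Rockafellar augmented Lagrangian, with event-driven ODE
    simulation of bolus, infusion and lagged administrations. Includes
    constraint types acting on a time window, a time point, a running mean,
    or the duration a state spends below a threshold, plus bundled example
    models, analytic toy problems and a brute-force grid oracle for
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
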