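Package: catflow
Title: Compile Categorical Generative Models into Stochastic and Chemical Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for treating a prescribed steady-state joint distribution
    over binary chemical species as a generative model and compiling it into
    dynamics: exact master equations over categorical distributions (with
    solenoidal/dissipative flow decomposition and variational free energy),
    mean-field message-passing operators restricted to Markov blankets,
    mass-action and Michaelis-Menten ODE systems with model-derived rate
    constants, and multi-reaction metabolic networks supporting lesion and
    diaschisis analyses. Model specifications are read and written as YAML,
    trajectories as CSV, and assembled mass-action networks can be exported
    to SBML Level 3.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    yaml,
    xml2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    Matrix
Config/testthat/edition: 3
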