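Package: myocyte
Title: Cardiac Myocyte Electrophysiology from Annotated CellML-Style Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Converts annotated CellML-subset descriptions of cardiac
    cellular electrophysiology models into a standardized symbolic ODE
    representation with consistent units and a common interface (membrane
    voltage, capacitance, stimulus current, ionic currents).  Provides
    symbolic transforms for specialized integrators (Rush-Larsen,
    generalized Rush-Larsen, backward Euler with analytic Jacobians,
    lookup tables, partial evaluation), fixed-step and adaptive solvers,
    mixed root mean square (MRMS) accuracy benchmarking with timestep
    refinement, action potential biomarkers, steady-state pacing to the
    limit cycle, and 1D monodomain strand simulation by operator splitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    xml2,
    jsonlite,
    deSolve,
    stats,
    utils,
    compiler
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
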