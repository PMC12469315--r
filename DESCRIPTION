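Package: betafit
Title: Chemical Speciation, Titration Simulation and Stability-Constant
    Refinement for Metal-Ligand Equilibria
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Solution-equilibrium analysis for metal-ligand systems: a
    mass-balance speciation solver (Newton iteration on logarithmic free
    concentrations), a potentiometric-titration simulator with dilution
    and a full proton condition, nonlinear least-squares refinement of
    overall stability constants (log beta) from titration curves with
    species-model ranking, stepwise equilibrium-constant (log Ke)
    bookkeeping from reaction strings, and a seeded synthetic-titration
    generator.  Equilibrium models for the Cu(II)/tyrosine binary system
    and the Cu(II)/tyrosine/adenosine, /AMP, /ADP and /ATP ternary
    systems (0.1 M KNO3, 20 C) are bundled as ready-made fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
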