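Package: diazokin
Title: Stopped-Flow Kinetics and Nucleophilicity Scale Analysis for
    Diazonium Coupling Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for electrophilic aromatic substitution
    kinetics measured by stopped-flow spectrophotometry: extraction of
    pseudo-first-order rate constants from single-exponential absorbance
    traces, second-order rate constants from concentration dependences,
    acid-base speciation correction of rate constants, kinetic isotope
    effect ratios, and linear free-energy analyses (Hammett, Yukawa-Tsuno,
    Mayr-Patz) culminating in a sigma-plus-based predictive model of
    nucleophilicity parameters.  Includes a mechanistic simulator of the
    two-step addition-elimination pathway for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
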