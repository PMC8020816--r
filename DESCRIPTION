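Package: glucakin
Title: Minimal Model of Glucagon Kinetics During an Oral Glucose
    Tolerance Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and estimation tools for a two-compartment
    minimal model of plasma glucagon kinetics during an oral glucose
    tolerance test (OGTT). Glucagon suppression is driven by the rate of
    change of C-peptide in a compartment remote from plasma through a
    time-varying alpha-cell insulin-sensitivity parameter. The package
    provides an exact discrete-time simulator with an independent
    adaptive ODE cross-check, a regularized multistart nonlinear
    least-squares estimator with asymptotic confidence intervals and
    data-driven selection of the regularization weights, a constrained
    Monte Carlo virtual-population generator, and population-level
    analyses (areas under the curve, sensitivity-versus-exposure
    regression, OGTT-duration sensitivity testing).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    MASS,
    minpack.lm,
    nortest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
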