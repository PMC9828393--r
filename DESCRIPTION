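Package: gradresp
Title: Parametric Non-Linear Models of Species' Responses Along Environmental Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits flexible parametric models of a single species' abundance
    response along an environmental or spatial gradient. Unimodal and bimodal
    mean functions (hyperbolic-secant based, Gaussian, Gaussian mixture,
    bounded beta, hierarchical-logistic, uniform, constant) are coupled with
    error distributions tailored to ecological data types (counts, biomass or
    densities, percent cover, presence/absence), including over-dispersed and
    zero-inflated families whose excess-zero probability may be linked to the
    mean. Estimation is by maximum likelihood (simulated annealing followed by
    quasi-Newton refinement), with AIC/AICc/BIC model selection over grids of
    mean-by-error combinations, standard errors and confidence intervals from
    the observed information matrix, stratified jackknife or bootstrap, and a
    simulation toolkit for coverage and bias experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
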