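Package: telodyn
Title: Telomere Length Dynamics and Stem Cell Division-Mode Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the attrition of average telomere length in hematopoietic
    stem cells as a truncated (generalised) Poisson compartment process with
    symmetric and asymmetric cell divisions. Provides closed-form
    state-occupancy distributions, moments and wave maxima, an individual-based
    stochastic simulator, generators for synthetic Flow-FISH-like cohort data
    and Q-FISH-like single-cell telomere length distributions, and inference
    tools: nonlinear least-squares fits of the mean telomere length decay,
    approximate Bayesian computation by rejection sampling, AIC/BIC model
    selection, and per-individual telomere-length distribution fits with
    derived telomere loss rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
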