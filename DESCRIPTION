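Package: isingbet
Title: Ising Network Simulation and the Consequences of Estimation Assumptions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates binary data from Ising models (Curie-Weiss, random
    sparse) and from a multidimensional item response model of two comorbid
    disorders, and estimates Ising networks with five methods: unregularized
    nodewise logistic regression, L1-penalized nodewise regression with
    extended-BIC selection (eLasso), Poisson log-linear fitting of the full
    contingency table, low-rank pseudolikelihood approximation, and
    elastic-net with cross-validation. Recovery of the generating network is
    scored by edge sensitivity, specificity, weight error and density, and a
    study pipeline reruns the sparse-versus-dense simulation designs at
    configurable scale. Includes the exact mixture representation linking the
    Curie-Weiss model to a unidimensional Rasch model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    pracma,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
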