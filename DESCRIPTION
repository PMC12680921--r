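Package: deformgnn
Title: Equivariant Graph Neural Networks for Soft-Tissue Deformation and
    Force Estimation over Heterogeneous Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts soft-tissue surface deformation and probe contact
    force from sparse point clouds with a conditional E(n)-equivariant
    graph neural network. Surface points carry binary tissue-composition
    depth profiles (soft silicone over rigid bone-like structure) so the
    model is aware of the anatomy beneath each point, and the probe's
    contact line conditions every layer. Includes an analytic
    heterogeneous-indentation data generator that stands in for
    finite-element simulations, weighted displacement/force training with
    location-stratified splits, transfer-learning utilities, and an
    evaluation suite covering rotated and cross-resolution test protocols
    plus equivariance audits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    jsonlite,
    ggplot2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
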