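Package: dendritenet
Title: Deep Learning with Segregated Dendrites in Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates near-continuous-time spiking neural networks whose hidden
    neurons integrate feedforward input in basal dendritic compartments and
    top-down feedback in electrotonically segregated apical compartments, and
    trains them with local, plateau-potential-driven weight updates so that
    credit assignment is achieved without weight transport. Provides the
    compartmental voltage dynamics, double-exponential synaptic filtering,
    Poisson spike generation, forward/target phase scheduling, the local
    learning rules with random fixed feedback weights (plus sparse, symmetric
    and noisy-symmetric variants), a backpropagation oracle with update-angle
    comparison, hidden/output loss-coordination analysis, a Jacobian-product
    eigenvalue monitor, a Monte-Carlo check of the firing-rate lemma, MNIST
    IDX readers and a class-structured synthetic dataset generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
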