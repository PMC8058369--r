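Package: cerebscaffold
Title: Cerebellar Scaffold Spiking-Network Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and simulates a scaffold model of the cerebellar
    microcircuit: stochastic cell placement in a layered 3-D volume,
    geometric structural connectivity stored as per-connection-type
    compressed sparse row matrices, conductance-based leaky
    integrate-and-fire dynamics with exponential-decay synapses solved by
    forward Euler at 0.1 ms with 1 ms spike exchange, and bidirectional
    plasticity (LTD/LTP) at parallel fiber-Purkinje cell synapses gated by
    climbing-fiber activity. Includes the two reference experiments:
    a mossy-fiber burst-response protocol with per-population firing-rate
    tables, and 300-trial optokinetic-response gain adaptation with
    trial-wise cosine-fitted learning curves. Results are returned as
    tibbles with broom-style tidiers and ggplot2 plotting methods; a thin
    command-line interface is included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
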