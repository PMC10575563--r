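Package: ratechannel
Title: Poisson Rate-Code Channel Simulation with an Entropy-Threshold Ideal-Observer Decoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates information transmission over an array of Poisson
    processes (a neural rate code): symbols are encoded as firing-rate vectors
    stored in a codebook, spikes are generated in discrete time bins, and a
    Bayesian ideal observer accumulates counts, updates a posterior over
    symbols, and commits to the most probable symbol once posterior entropy
    falls below a threshold. Decoding times reproduce classic response-time
    regularities: right-skewed time distributions, the Hick-Hyman law,
    linearity of time with information gain (surprisal), the power law of
    practice via Dirichlet prior updating, speed-accuracy trade-offs, and
    Stroop-like congruence effects via multiplexed rate vectors. Also includes
    a reinforcement-learning module that learns codebooks under time, accuracy
    and spike costs and quantifies the sparsity of learned codes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
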