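Package: rchp
Title: Reward-Modulated Hebbian Learning with Rare Correlations and Eligibility Traces
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates rate-based neural networks that solve the distal reward
    problem through rarely correlating Hebbian plasticity: thresholded detection
    of rare lagged pre-post activity correlations creates slowly decaying,
    synapse-specific eligibility traces, and a delayed reward-driven
    neuromodulatory signal converts those traces into weight changes. Includes
    homeostatic adaptation of the correlation thresholds toward a target rare
    event rate, closed-loop classical-conditioning and operant-conditioning
    scenarios with Poisson stimulus schedules, winner-take-all action selection
    with action-to-network feedback, behavior reversal under punishment, a
    combinatorial synapse-population model of credit assignment under delayed
    reward, and recording, summary and serialization tools.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
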