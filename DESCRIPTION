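Package: actinf
Title: Active Inference Agents with Planning, Counterfactual Learning, and
    Entropy-Based Arbitration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Discrete-state active inference agents for sequential
    decision-making under a POMDP generative model.  Implements a
    dynamic-programming planner that evaluates expected free energy
    backward over a finite horizon, a counterfactual learner that
    acquires a risk-modulated state-action mapping without planning,
    and a mixed agent that arbitrates between the two through a
    state-dependent bias driven by the Shannon entropies of their
    action distributions.  Ships self-contained grid-world and
    cart-pole testbeds with scheduled environment mutations, baseline
    oracles (breadth-first search, random walk), and a seeded
    experiment runner for learning-curve, risk-trace and bias-trace
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
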