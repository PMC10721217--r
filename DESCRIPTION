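Package: rvtrace
Title: Efficiency of Monosynaptic Rabies Tracing at the Synaptic Level
Version: 0.1.0
Authors@R:
    person("rvtrace", "maintainers", email = "rvtrace@example.org",
           role = c("aut", "cre"))
Description: Models the relationship between the fraction of synaptic
    contacts labeled by glycoprotein-trans-complemented rabies tracing
    (synaptic fraction, SF), the fraction of presynaptic input neurons
    labeled (input fraction, IF), and the probability that rabies crosses
    a single synaptic contact (unitary synaptic efficiency, U). Provides
    the closed-form two-population multiplicity model and its mixture
    generalization, solvers and parameter sweeps, a distance-binned
    correction for inputs shared between nearby starter cells, a seeded
    Monte Carlo simulator of viral spread over explicit starter/input
    contact graphs that serves as a brute-force oracle for the analytics,
    generators for synthetic circuits and puncta-colocalization count
    tables, and the quantification statistics used on such tables
    (apposition detection, per-neuron colocalization summaries,
    background-corrected SF, and Wilcoxon rank-sum comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
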