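Package: braincosim
Title: Multi-Scale Co-Simulation of Seizure Generation and Whole-Brain Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Couples a biophysical potassium-bath neuron model (Hodgkin-Huxley
    dynamics with intra-/extracellular ion concentration bookkeeping, a
    Na+/K+ pump and an external potassium bath) and networks of such cells to
    a reduced Wong-Wang neural mass model running on a delayed structural
    connectome. One connectome region can be replaced by a spiking proxy
    population; discrete spikes and continuous region activity are translated
    across the boundary with binned or calcium-filter rate converters and a
    stochastic rate-to-event generator, exchanged on an epoch schedule set by
    the smallest inter-region delay. Includes seizure detection on region
    activity, onset timing and propagation-latency mapping, a synthetic
    connectome generator, and readers/writers for connectome and trace
    formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
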