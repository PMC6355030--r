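Package: mrochannel
Title: Information Rates of a Depressing Synaptic Release Site
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Models a single synaptic release site under short-term depression
    as a finite-state binary asymmetric channel whose state is the last L
    release outcomes. Computes exact mutual information rates and
    energy-normalized information rates of the channel from the stationary
    distribution of the underlying 2^L-state Markov chain, together with
    no-depression baselines, parameter-sweep analyses (capacity, optimal
    input rate, effective memory length, rate-energy functional categories),
    Monte-Carlo simulation of spike and release trains, an alternative
    quantized-probability channel formulation, and presets for three
    experimentally characterized synapses (hippocampal autapse, calyx of
    Held, corticostriatal synapse under dopamine).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
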