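Package: nsdyn
Title: Trial-to-Trial Dynamics of Evoked Network Spikes on Multi-Electrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for trial-to-trial variability of evoked network
    spikes in cultured cortical networks recorded on multi-electrode arrays.
    Detects network spikes by thresholding the population firing rate, extracts
    sub-second response features (latency to the post-stimulus histogram peak,
    decay duration to a fixed rate floor, local response probability), and
    quantifies minutes-scale structure through Fano-factor scaling of network
    spike counts with power-law exponent fitting, inter-event-interval shuffled
    surrogates, serial-index autocorrelation with a warped time axis, and
    latency-decay plane trajectories. Includes a seeded doubly-stochastic
    generator of surrogate multi-electrode recordings (Ornstein-Uhlenbeck,
    oscillatory, and fractional-Gaussian-noise latent modes) with ground truth
    for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
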