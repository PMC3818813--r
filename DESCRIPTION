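Package: ventnet
Title: Two-Layer Firing-Rate Network Model of Audiovisual Ventriloquism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-layer firing-rate network of visual and auditory
    neurons with Mexican-hat lateral connectivity and excitatory cross-modal
    coupling, reproducing the ventriloquism effect (visual capture of perceived
    sound location), the ventriloquism aftereffect induced by threshold-gated
    Hebbian plasticity with synaptic normalization, and the aftereffect's
    generalization across sound frequencies as a function of stimulus intensity.
    Provides stimulus builders, steady-state integration, adaptation protocols,
    barycenter population decoding, tuning-curve and frequency-response-area
    analysis, and tidy result tables with ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
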