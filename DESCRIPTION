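Package: micturinet
Title: Conductance-Based Simulation of the Spinal Micturition Circuit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hodgkin-Huxley network simulation of the spinal and brainstem
    circuit controlling urine storage and voiding. Reproduces healthy
    micturition, detrusor-sphincter dyssynergia after suprasacral spinal
    cord injury, dripping incontinence after conus injury, and the acute,
    frequency-dependent effects of transcutaneous magnetic stimulation
    (TMS), modelled as a transient sodium-conductance perturbation of
    lumbar interneurons. Includes a fixed-step RK4 network integrator,
    a multi-compartment cable model of the pelvic afferent pathway,
    lesion and synaptic-plasticity overlays, TMS pulse-train and
    bladder-afferent stimulus generators, and spike-train metrics
    (firing rates, bursts, coactivation, voiding-event detection).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
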